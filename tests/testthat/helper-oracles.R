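# Independent oracles used across the suite. These deliberately take
# different computational routes than the package implementation.

# Brute-force Newton-Raphson for weighted logistic regression: explicit
# score/Hessian iteration, no IRLS, no glm.
newton_logit <- function(X, y, w = rep(1, length(y)), tol = 1e-12,
                         maxit = 200L) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    score <- drop(t(X) %*% (w * (y - mu)))
    H <- t(X) %*% (X * (w * mu * (1 - mu)))
    step <- solve(H, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# Average ranks computed from first principles (counting, not rank()),
# then Pearson via stats::cor.
brute_spearman <- function(x, y) {
  avg_rank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2,
           numeric(1L))
  }
  stats::cor(avg_rank(x), avg_rank(y))
}

# Full-vocabulary cosine scan for lexicon expansion: for one seed token,
# the expected expanded set at threshold tau and budget k.
brute_expand_one <- function(space, seed_token, tau, k, exclude) {
  q <- space$vectors[match(seed_token, space$vocabulary), ]
  sims <- vapply(seq_along(space$vocabulary), function(i) {
    v <- space$vectors[i, ]
    den <- sqrt(sum(v^2)) * sqrt(sum(q^2))
    if (den == 0) 0 else sum(v * q) / den
  }, numeric(1L))
  df <- data.frame(token = space$vocabulary, sim = sims,
                   stringsAsFactors = FALSE)
  df <- df[df$token != seed_token & df$sim >= tau &
             !df$token %in% exclude, , drop = FALSE]
  df <- df[order(-df$sim, df$token), , drop = FALSE]
  utils::head(df$token, k)
}

# small, fast generator configuration for unit tests
quick_cfg <- function(seed = 42L, ...) {
  synth_config(n_respondents = 400L, n_users = 800L, rng_seed = seed, ...)
}

# tiny deterministic lexicon used where expansion is not under test
tiny_lexicon <- function() {
  seeds_as_lexicon(build_seed_sets(list(
    diminished_interest = "keine lust",
    depressed_mood = c("schwermut", "aussichtslos"),
    insomnia_hypersomnia = "einschlafprobleme",
    fatigue_energy_loss = "energielos",
    worthlessness_guilt = c("wertlos", "enttäuschung")
  )))
}

box1_tweets <- function() {
  tibble::tibble(
    text = c(
      "Ich habe keine Lust mehr auf Praktikum? So viel Heteronormativität ertrage ich nicht.",
      "Es ist aussichtslos. Ich bin ins Mark erschüttert.",
      "Sind das nur Einschlafprobleme, oder leide ich unter Insomnie?",
      "Ja schon...Ich fühle mich immer so energielos.",
      "Du denkst du könntest mich verletzen? Bro ich bin die Enttäuschung der Familie.",
      paste("Ich denke nur darüber nach, wie es gefunden werden würde,",
            "wie sich meine Schwester fühlte. Schon mit dem Vater weg und",
            "jetzt bin ich tot. Die Szene von mir tot. Ich kann es nicht",
            "ertragen zu sterben, weil ich weiß, dass sie traurig sind")),
    timestamp = as.Date("2020-03-25") + 0:5,
    user_id = sprintf("b%d", 1:6),
    is_retweet = FALSE,
    sex = "female", age_group = "18-24", region = NA_character_
  )
}

box1_expected <- list(
  "diminished_interest", "depressed_mood", "insomnia_hypersomnia",
  "fatigue_energy_loss", "worthlessness_guilt", "worthlessness_guilt"
)
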