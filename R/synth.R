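#' Configuration for the synthetic-data generators
#'
#' Bundles every knob of the synthetic survey cohort, tweet stream and
#' enrichment corpus. Defaults emulate the study conditions of the first
#' German COVID-19 social-contact ban window (calendar weeks 1--31 of
#' 2020, ban weeks 12--18): symptom base rates and period offsets are
#' derived from the published period-level margins of both sources, the
#' survey sex/age composition from the survey sample description
#' (51.7% female, 50+ modal), and the tweet-stream composition from the
#' Twitter sample description (83.9% female, 18--24 modal, 96% of users
#' contributing a single tweet, 1--10 tweets per user per week).
#'
#' @param n_respondents Number of synthetic survey respondents.
#' @param n_users Number of synthetic Twitter users.
#' @param window A [study_window()] (weeks, dates, period bounds).
#' @param symptom_base_rates Named probability vector: survey-side
#'   P(affected) in the *before* period, per symptom.
#' @param period_effects Named list, symptom -> numeric triple of log-odds
#'   offsets `c(before, during, after)` applied to the survey outcome
#'   (before is the reference, 0).
#' @param tweet_symptom_rates Named probability vector summing to 1: the
#'   share of symptom tweets attributed to each symptom in the *before*
#'   period.
#' @param tweet_period_effects Named list, symptom -> log-rate offsets
#'   `c(before, during, after)` multiplying the tweet-side symptom
#'   intensity.
#' @param demo_effects List with `sex_female` (log-odds offset for women),
#'   `age` (named offsets per harmonized age level, youngest keyed
#'   `"<18"`), and `female_young` (extra offset for women aged 18--24);
#'   applied to both sources, encoding the elevated risk among young adult
#'   women.
#' @param survey_sex_probs,survey_age_probs,tweet_sex_probs,tweet_age_probs
#'   Demographic marginals of the two samples (named, normalized
#'   internally).
#' @param p_single_tweet P(a user contributes exactly 1 tweet); the
#'   remaining mass decays geometrically over 2--10 tweets.
#' @param tweets_per_user Optional explicit length-10 probability vector
#'   over 1--10 tweets, overriding `p_single_tweet`.
#' @param self_reference_rate Probability a keyword-bearing synthetic text
#'   is phrased in the first person.
#' @param retweet_rate Probability a generated record is a retweet.
#' @param weight_sdlog Log-scale SD of the log-normal survey weights
#'   (mean-1 on the natural scale).
#' @param severity_probs Probabilities of graded responses 1/2/3 given a
#'   respondent is affected.
#' @param rng_seed Integer seed; every generator is deterministic given it.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_respondents = 9011L,
                         n_users = 80000L,
                         window = study_window(),
                         symptom_base_rates = c(
                           diminished_interest  = 0.38,
                           depressed_mood       = 0.27,
                           insomnia_hypersomnia = 0.50,
                           fatigue_energy_loss  = 0.54,
                           worthlessness_guilt  = 0.14),
                         period_effects = list(
                           diminished_interest  = c(0,  0.084, 0),
                           depressed_mood       = c(0,  0.050, 0),
                           insomnia_hypersomnia = c(0, -0.120, -0.040),
                           fatigue_energy_loss  = c(0, -0.160, -0.080),
                           worthlessness_guilt  = c(0, -0.086, 0)),
                         tweet_symptom_rates = c(
                           diminished_interest  = 0.268,
                           depressed_mood       = 0.163,
                           insomnia_hypersomnia = 0.163,
                           fatigue_energy_loss  = 0.349,
                           worthlessness_guilt  = 0.057),
                         tweet_period_effects = list(
                           diminished_interest  = c(0,  0.002, 0.146),
                           depressed_mood       = c(0,  0.073, 0.163),
                           insomnia_hypersomnia = c(0, -0.112, 0.059),
                           fatigue_energy_loss  = c(0, -0.109, 0.094),
                           worthlessness_guilt  = c(0, -0.148, 0.090)),
                         demo_effects = list(
                           sex_female = 0.30,
                           age = c("<18" = 0, "18-24" = 0.20, "25-34" = 0,
                                   "35-49" = -0.10, "50+" = -0.20),
                           female_young = 0.30),
                         survey_sex_probs = c(female = 0.517, male = 0.483),
                         survey_age_probs = c("15-17" = 0.045, "18-24" = 0.084,
                                              "25-34" = 0.137, "35-49" = 0.199,
                                              "50+" = 0.536),
                         tweet_sex_probs = c(female = 0.839, male = 0.161),
                         tweet_age_probs = c("10-17" = 0.128, "18-24" = 0.577,
                                             "25-34" = 0.129, "35-49" = 0.106,
                                             "50+" = 0.060),
                         p_single_tweet = 0.96,
                         tweets_per_user = NULL,
                         self_reference_rate = 0.96,
                         retweet_rate = 0.03,
                         weight_sdlog = 0.5,
                         severity_probs = c(0.6, 0.3, 0.1),
                         rng_seed = 1L) {
  chk_prob <- function(x, field, open = TRUE) {
    if (any(!is.finite(x)) ||
        (open && any(x <= 0 | x >= 1)) ||
        (!open && any(x < 0 | x >= 1)))
      abort_config(field, "probabilities outside the admissible range")
  }
  if (!is.numeric(n_respondents) || n_respondents < 1)
    abort_config("n_respondents", "must be a positive integer")
  if (!is.numeric(n_users) || n_users < 1)
    abort_config("n_users", "must be a positive integer")
  if (!inherits(window, "study_window"))
    abort_config("window", "must be a study_window()")
  chk_prob(symptom_base_rates, "symptom_base_rates")
  if (is.null(names(symptom_base_rates)) ||
      !all(names(symptom_base_rates) %in% phq_symptoms))
    abort_config("symptom_base_rates", "must be named by PHQ symptoms")
  rates <- tweet_symptom_rates / sum(tweet_symptom_rates)
  chk_prob(rates, "tweet_symptom_rates")
  if (is.null(tweets_per_user)) {
    if (p_single_tweet <= 0 || p_single_tweet >= 1)
      abort_config("p_single_tweet", "must be in (0,1)")
    tail_w <- 0.5^(0:8)
    tweets_per_user <- c(p_single_tweet,
                         (1 - p_single_tweet) * tail_w / sum(tail_w))
  }
  if (length(tweets_per_user) != 10L || any(tweets_per_user < 0) ||
      abs(sum(tweets_per_user) - 1) > 1e-8)
    abort_config("tweets_per_user",
                 "must be a probability vector over 1..10 tweets")
  if (!is.finite(self_reference_rate) || self_reference_rate <= 0 ||
      self_reference_rate > 1)
    abort_config("self_reference_rate", "must be in (0, 1]")
  chk_prob(retweet_rate, "retweet_rate", open = FALSE)
  if (abs(sum(severity_probs) - 1) > 1e-8 || any(severity_probs < 0))
    abort_config("severity_probs", "must sum to 1")
  if (!is.numeric(rng_seed) || is.na(rng_seed))
    abort_config("rng_seed", "must be an integer")

  structure(list(
    n_respondents = as.integer(n_respondents),
    n_users = as.integer(n_users),
    window = window,
    symptom_base_rates = symptom_base_rates,
    period_effects = period_effects,
    tweet_symptom_rates = rates,
    tweet_period_effects = tweet_period_effects,
    demo_effects = demo_effects,
    survey_sex_probs = survey_sex_probs / sum(survey_sex_probs),
    survey_age_probs = survey_age_probs / sum(survey_age_probs),
    tweet_sex_probs = tweet_sex_probs / sum(tweet_sex_probs),
    tweet_age_probs = tweet_age_probs / sum(tweet_age_probs),
    tweets_per_user = tweets_per_user,
    self_reference_rate = self_reference_rate,
    retweet_rate = retweet_rate,
    weight_sdlog = weight_sdlog,
    severity_probs = severity_probs,
    rng_seed = as.integer(rng_seed)
  ), class = "synth_config")
}

# run expr under a given seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# log-odds / log-rate linear predictor shared by both generators
demo_offset <- function(cfg, sex, age_group) {
  de <- cfg$demo_effects
  age_h <- ifelse(age_group %in% c("15-17", "10-17"), "<18", age_group)
  off <- de$age[age_h]
  off[is.na(off)] <- 0
  unname(off) +
    de$sex_female * (sex == "female") +
    de$female_young * (sex == "female" & age_h == "18-24")
}

#' Generate a synthetic survey cohort
#'
#' Emulates a cross-sectional health-survey subsample fielded over the
#' study window: each respondent gets a uniform calendar week, sex and age
#' group from the configured marginals, a mean-1 log-normal survey weight,
#' and graded 0--3 responses to the five retained PHQ-8 items drawn so that
#' P(response >= 1) follows a logistic model with the configured base
#' rate, contact-ban period offset and demographic offsets.
#'
#' @param config A [synth_config()].
#' @return Tibble with columns `id`, `week`, `sex`, `age_group`, `weight`
#'   and the five item columns `item_interest`, `item_mood`, `item_sleep`,
#'   `item_fatigue`, `item_worth` (integer 0--3). Byte-identical across
#'   calls with the same config.
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$rng_seed, {
    n <- config$n_respondents
    weeks <- config$window$weeks
    week <- sample(weeks, n, replace = TRUE)
    sex <- sample(names(config$survey_sex_probs), n, replace = TRUE,
                  prob = config$survey_sex_probs)
    age <- sample(names(config$survey_age_probs), n, replace = TRUE,
                  prob = config$survey_age_probs)
    weight <- rlnorm(n, meanlog = -config$weight_sdlog^2 / 2,
                     sdlog = config$weight_sdlog)
    period <- label_periods(week, config$window)
    demo <- demo_offset(config, sex, age)

    out <- tibble::tibble(
      id = sprintf("r%05d", seq_len(n)),
      week = as.integer(week), sex = sex, age_group = age, weight = weight
    )
    for (sym in names(config$symptom_base_rates)) {
      eta <- qlogis(config$symptom_base_rates[[sym]]) +
        config$period_effects[[sym]][as.integer(period)] + demo
      affected <- rbinom(n, 1L, plogis(eta))
      grade <- sample(1:3, n, replace = TRUE, prob = config$severity_probs)
      out[[symptom_items[[sym]]]] <- as.integer(affected * grade)
    }
    out
  })
}

# carrier sentences; every first-person template contains a token from the
# default self-reference vocabulary, every third-person template none
fp_templates <- c(
  "Ich fühle mich seit Tagen %s.",
  "Ich habe gerade wieder %s.",
  "Bei mir ist es nur noch %s, ehrlich.",
  "Ich leide echt unter %s.",
  "Irgendwie bin ich nur noch %s unterwegs."
)
tp_templates <- c(
  "Er wirkt seit Tagen total %s.",
  "Sie redet staendig ueber %s.",
  "Die Nachbarin klagt schon wieder ueber %s.",
  "Der Typ da drueben wirkt so %s.",
  "Das klingt stark nach %s."
)

#' Generate a synthetic tweet stream
#'
#' Emulates the keyword-collected tweet corpus: users contribute 1--10
#' tweets within a single calendar week (96% single-tweet by default),
#' each tweet text is assembled from a carrier-sentence template so that
#' it contains exactly one lexicon keyword of its symptom, is phrased in
#' the first person with probability `self_reference_rate` (third person
#' otherwise), and is flagged/prefixed as a retweet with probability
#' `retweet_rate`. Weekly per-symptom intensities follow
#' `tweet_symptom_rates` scaled by `exp(tweet_period_effects)`. Single-word
#' keywords are occasionally rendered as hashtags.
#'
#' @param config A [synth_config()].
#' @param lexicon A `symptom_lexicon` with at least one keyword for every
#'   symptom with positive rate.
#' @return Tibble of tweet records: `text`, `timestamp` (`Date`),
#'   `user_id`, `is_retweet`, `sex`, `age_group`, `region`, plus
#'   generator ground truth `truth_symptom` and `truth_self_ref` (used by
#'   validation, ignored by the pipeline).
#' @export
generate_tweets <- function(config, lexicon = default_lexicon()) {
  stopifnot(inherits(config, "synth_config"))
  syms <- names(config$tweet_symptom_rates)[config$tweet_symptom_rates > 0]
  kw_by_sym <- split(lexicon$keyword, lexicon$symptom)[syms]
  if (any(vapply(kw_by_sym, function(k) length(k) == 0L || is.null(k),
                 logical(1L))))
    stop("lexicon has no keywords for at least one symptom", call. = FALSE)

  with_seed(config$rng_seed + 1L, {
    n_users <- config$n_users
    weeks <- config$window$weeks
    u_week <- sample(weeks, n_users, replace = TRUE)
    u_sex <- sample(names(config$tweet_sex_probs), n_users, replace = TRUE,
                    prob = config$tweet_sex_probs)
    u_age <- sample(names(config$tweet_age_probs), n_users, replace = TRUE,
                    prob = config$tweet_age_probs)
    u_k <- sample(1:10, n_users, replace = TRUE, prob = config$tweets_per_user)

    idx <- rep(seq_len(n_users), u_k)
    n_tw <- length(idx)
    week <- u_week[idx]
    sex <- u_sex[idx]
    age <- u_age[idx]
    period <- label_periods(week, config$window)

    # per-period symptom mixture: share * exp(period log-rate offset)
    per_mat <- vapply(syms, function(s)
      config$tweet_symptom_rates[[s]] *
        exp(config$tweet_period_effects[[s]]), numeric(3L))
    symptom <- character(n_tw)
    for (p in 1:3) {
      sel <- as.integer(period) == p
      if (any(sel))
        symptom[sel] <- sample(syms, sum(sel), replace = TRUE,
                               prob = per_mat[p, ])
    }

    keyword <- vapply(symptom, function(s) {
      kws <- kw_by_sym[[s]]
      kws[sample.int(length(kws), 1L)]
    }, character(1L), USE.NAMES = FALSE)
    hash <- runif(n_tw) < 0.1 & !grepl(" ", keyword, fixed = TRUE)
    keyword_txt <- ifelse(hash, paste0("#", keyword), keyword)

    self_ref <- runif(n_tw) < config$self_reference_rate
    tmpl <- ifelse(self_ref,
                   fp_templates[sample.int(length(fp_templates), n_tw,
                                           replace = TRUE)],
                   tp_templates[sample.int(length(tp_templates), n_tw,
                                           replace = TRUE)])
    text <- sprintf(tmpl, keyword_txt)

    is_rt <- runif(n_tw) < config$retweet_rate
    text[is_rt] <- paste0("RT @nutzer", sample(99999L, sum(is_rt),
                                               replace = TRUE), ": ",
                          text[is_rt])

    # uniform day within the week, restricted to the study window
    wstart <- iso_week_start(week, config$window$year)
    lo <- pmax(as.integer(wstart), as.integer(config$window$start))
    hi <- pmin(as.integer(wstart) + 6L, as.integer(config$window$end))
    day <- lo + floor(runif(n_tw) * (hi - lo + 1L))
    timestamp <- as.Date(day, origin = "1970-01-01")

    region <- sample(c("BE", "BY", "NW", "BW", NA), n_tw, replace = TRUE,
                     prob = c(0.1, 0.2, 0.25, 0.1, 0.35))

    tibble::tibble(
      text = text, timestamp = timestamp,
      user_id = sprintf("u%06d", idx),
      is_retweet = is_rt, sex = sex, age_group = age, region = region,
      truth_symptom = symptom, truth_self_ref = self_ref
    )
  })
}

# German filler vocabulary partitioned into symptom-specific context pools
context_vocab <- c(
  "leben", "alltag", "gedanken", "morgen", "abend", "arbeit", "woche",
  "gefuehl", "zeit", "kopf", "herz", "tage", "stunden", "momente",
  "pause", "lage", "stimmungstief", "phase", "zustand", "innere",
  "druck", "last", "leere", "stille", "dunkel", "schwere", "nacht",
  "bett", "traum", "wachliegen", "grübeln", "schlaf", "augen", "körper",
  "energie", "kraft", "antrieb", "akku", "feierabend", "müde",
  "selbstbild", "wert", "schuld", "zweifel", "versagen", "scham",
  "freude", "hobby", "lust", "interesse", "motivation", "spass"
)
default_distractor_words <- function() c(
  "fahrrad", "rezept", "fussball", "wetterbericht", "steuern", "urlaub",
  "katze", "garten", "bahnhof", "computer", "serie", "kaffee"
)

#' Generate a synthetic enrichment corpus
#'
#' Stands in for a scraped depression-forum corpus: emits short documents
#' in which each related word co-occurs with the same symptom-specific
#' context tokens as the seed words of its symptom (so embedding-based
#' expansion can discover it), plus distractor documents built over a
#' disjoint context pool. One document per output element.
#'
#' @param config A [synth_config()] (only `rng_seed` is used).
#' @param seed_words Named list symptom -> seed words (or a `seed_sets`
#'   tibble).
#' @param related_words Named list symptom -> related words to embed near
#'   that symptom's seeds.
#' @param n_docs_per_word Documents generated per target word. Default 30.
#' @param distractor_words Character vector of off-topic words (may be
#'   empty for a competition-free corpus).
#' @return Character vector of documents.
#' @export
generate_corpus <- function(config, seed_words, related_words,
                            n_docs_per_word = 30L,
                            distractor_words = default_distractor_words()) {
  stopifnot(inherits(config, "synth_config"))
  if (inherits(seed_words, "seed_sets"))
    seed_words <- split(seed_words$keyword, seed_words$symptom)
  if (!is.list(related_words)) related_words <- list(all = related_words)
  if (length(unlist(seed_words)) == 0L)
    stop("empty seed word list", call. = FALSE)
  if (length(unlist(related_words)) == 0L)
    stop("empty related word list", call. = FALSE)

  groups <- union(names(seed_words), names(related_words))
  n_ctx <- 8L
  if (length(groups) * n_ctx > length(context_vocab))
    n_ctx <- max(3L, length(context_vocab) %/% length(groups))

  with_seed(config$rng_seed + 2L, {
    docs <- character(0)
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      pool <- context_vocab[((gi - 1L) * n_ctx + 1L):(gi * n_ctx)]
      targets <- c(seed_words[[g]], related_words[[g]])
      targets <- tolower(targets[!is.na(targets)])
      for (w in targets) {
        for (d in seq_len(n_docs_per_word)) {
          ctx <- sample(pool, 3L)
          docs <- c(docs, paste(ctx[1L], ctx[2L], w, ctx[3L]))
        }
      }
    }
    if (length(distractor_words)) {
      dpool <- c("regen", "sonne", "strasse", "laden", "termin", "plan",
                 "verein", "stadt")
      for (w in tolower(distractor_words)) {
        for (d in seq_len(n_docs_per_word)) {
          ctx <- sample(dpool, 3L)
          docs <- c(docs, paste(ctx[1L], w, ctx[2L], ctx[3L]))
        }
      }
    }
    sample(docs)  # shuffle document order
  })
}
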