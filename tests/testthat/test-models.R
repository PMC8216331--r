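make_survey_data <- function(n = 400L, seed = 1L) {
  cfg <- synth_config(n_respondents = n, rng_seed = seed)
  survey_model_data(generate_survey(cfg), "fatigue_energy_loss",
                    cfg$window)
}

test_that("a covariate-free logit fit recovers logit of the weighted proportion", {
  d <- make_survey_data(600L, seed = 2L)
  fit <- fit_symptom_model(d, "binomial_logit", time_term = "none",
                           covariates = FALSE)
  p_w <- weighted.mean(d$y, d$weight)
  expect_equal(unname(coef(fit)), qlogis(p_w), tolerance = 1e-8)
  m <- predictive_margins(fit, at = 10)
  expect_equal(m$margin, p_w, tolerance = 1e-8)
})

test_that("IRLS coefficients equal brute-force Newton-Raphson on tiny data", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 24L
    # balanced cells keep the tiny design full-rank and non-separated
    d <- tibble::tibble(
      y = rbinom(n, 1L, 0.5),
      week = sample(1:31, n, replace = TRUE),
      sex = factor(rep(c("male", "female"), each = n / 2),
                   levels = c("male", "female")),
      age_group = factor(rep(c("18-24", "50+"), n / 2)),
      weight = runif(n, 0.5, 2))
    if (any(tapply(d$y, paste(d$sex, d$age_group), stats::var) == 0)) next
    d$period <- label_periods(d$week)
    fit <- fit_symptom_model(d, "binomial_logit", time_term = "none",
                             covariates = TRUE)
    X <- model.matrix(~ sex * age_group, d)
    oracle <- newton_logit(X, d$y, d$weight)
    expect_equal(unname(coef(fit)), unname(oracle), tolerance = 1e-6)
  }
})

test_that("polynomial time terms need 5 distinct weeks and interpolate exactly", {
  d <- tibble::tibble(y = rnorm(8), week = rep(1:4, 2), weight = 1)
  expect_error(add_polynomial_time(d), "unidentifiable")

  # gaussian fit over exactly 5 distinct weeks: poly4 interpolates cell means
  set.seed(3)
  d5 <- tibble::tibble(
    y = rnorm(50), week = rep(c(2L, 7L, 15L, 22L, 30L), each = 10L),
    period = label_periods(rep(c(2L, 7L, 15L, 22L, 30L), each = 10L)),
    sex = factor("male"), age_group = factor("18-24"), weight = 1)
  fit <- fit_symptom_model(d5, "gaussian_identity", time_term = "poly4",
                           covariates = FALSE)
  m <- predictive_margins(fit, at = c(2, 7, 15, 22, 30))
  means <- tapply(d5$y, d5$week, mean)
  expect_equal(m$margin, as.numeric(means), tolerance = 1e-8)
})

test_that("fitted values and margins are invariant to the polynomial center", {
  set.seed(4)
  d <- tibble::tibble(y = rnorm(60), week = rep(1:30, 2), weight = 1)
  d1 <- add_polynomial_time(d, center = 0)
  d2 <- add_polynomial_time(d, center = 15.5)
  f <- y ~ week_c1 + week_c2 + week_c3 + week_c4
  expect_equal(fitted(lm(f, d1)), fitted(lm(f, d2)), tolerance = 1e-8)
})

test_that("a linear weekly signal is reproduced by the degree-4 smoother", {
  # noise-free linear trend: the quartic fit must reproduce it exactly
  d <- tibble::tibble(y = 0.2 + 0.01 * (1:31), week = 1:31,
                      period = label_periods(1:31),
                      sex = factor("male"), age_group = factor("18-24"),
                      weight = 1)
  fit <- fit_symptom_model(d, "gaussian_identity", time_term = "poly4",
                           covariates = FALSE)
  m <- predictive_margins(fit, at = 1:31)
  expect_equal(m$margin, 0.2 + 0.01 * (1:31), tolerance = 1e-8)
})

test_that("rank-deficient designs error naming the aliased columns", {
  d <- make_survey_data(300L, seed = 5L)
  d$age_group <- factor(ifelse(d$sex == "female", "18-24", "50+"))
  expect_error(
    fit_symptom_model(d, "binomial_logit", time_term = "none"),
    "aliased")
})

test_that("separation is flagged, never silent", {
  d <- tibble::tibble(
    y = rep(c(0L, 1L), each = 20),
    week = rep(1:20, 2), period = label_periods(rep(1:20, 2)),
    sex = factor(rep(c("male", "female"), each = 20),
                 levels = c("male", "female")),
    age_group = factor(rep(c("18-24", "50+"), 20)), weight = 1)
  expect_warning(
    fit <- fit_symptom_model(d, "binomial_logit", time_term = "none"),
    "separation")
  expect_true(fit$separation)
})

test_that("period margins average observed covariates and bracket the estimate", {
  d <- make_survey_data(2000L, seed = 7L)
  fit <- fit_symptom_model(d, "binomial_logit", time_term = "period")
  m <- predictive_margins(fit, at = "period")
  expect_equal(m$level, c("before", "during", "after"))
  expect_true(all(m$margin > 0 & m$margin < 1))
  expect_true(all(m$ci_low < m$margin & m$margin < m$ci_high))
  # the weighted before-period mean is close to the before margin
  raw <- weighted.mean(d$y[d$period == "before"],
                       d$weight[d$period == "before"])
  expect_lt(abs(m$margin[1] - raw), 0.03)
})

test_that("delta-method margin SEs agree with a nonparametric bootstrap", {
  d <- make_survey_data(800L, seed = 8L)
  fit <- fit_symptom_model(d, "binomial_logit", time_term = "period")
  m <- predictive_margins(fit, at = "period")
  set.seed(99)
  boots <- replicate(200, {
    idx <- sample.int(nrow(d), replace = TRUE)
    fb <- fit_symptom_model(d[idx, ], "binomial_logit",
                            time_term = "period")
    predictive_margins(fb, at = "period")$margin
  })
  boot_se <- apply(boots, 1L, stats::sd)
  expect_true(all(abs(m$se - boot_se) / boot_se < 0.15))
})

test_that("the joint Wald statistic equals an independent quadratic form", {
  d <- make_survey_data(1500L, seed = 9L)
  fit <- fit_symptom_model(d, "binomial_logit", time_term = "period")
  w <- wald_period_test(fit)
  idx <- grep("^period", names(coef(fit)))
  b <- coef(fit)[idx]
  V <- vcov(fit)[idx, idx]
  # independent route: eigendecomposition-based inverse
  ev <- eigen(V, symmetric = TRUE)
  Vinv <- ev$vectors %*% diag(1 / ev$values, length(ev$values)) %*%
    t(ev$vectors)
  expect_equal(w$statistic, drop(t(b) %*% Vinv %*% b), tolerance = 1e-8)
  expect_equal(w$p_value, pchisq(w$statistic, 2, lower.tail = FALSE))
  # design-adjusted variant reports an F statistic
  wf <- wald_period_test(fit, df2 = 50)
  expect_equal(wf$statistic, w$statistic / 2, tolerance = 1e-12)
  expect_equal(wf$p_value, pf(w$statistic / 2, 2, 50, lower.tail = FALSE))
})

test_that("pairwise contrasts: self-contrast is null, others match margin diffs", {
  d <- make_survey_data(1500L, seed = 10L)
  fit <- fit_symptom_model(d, "binomial_logit", time_term = "period")
  ct <- pairwise_contrasts(fit)
  m <- predictive_margins(fit, at = "period")
  expect_equal(ct$estimate[ct$contrast == "before vs during"],
               m$margin[1] - m$margin[2], tolerance = 1e-10)
  self <- pairwise_contrasts(fit, pairs = list(c("during", "during")))
  expect_equal(self$statistic, 0)
  expect_equal(self$p_value, 1)
})

test_that("twitter cell data: gaussian fit margins live on the tweets/day scale", {
  cfg <- quick_cfg(seed = 11L)
  lex <- tiny_lexicon()
  tw <- generate_tweets(cfg, lex)
  cl <- suppressMessages(classify_tweets(tw, lex, window = cfg$window))
  d <- twitter_model_data(cl, "fatigue_energy_loss", cfg$window)
  expect_true(all(d$y >= 0))
  # covariate-free gaussian period margins are exactly the period cell means
  fit0 <- fit_symptom_model(d, "gaussian_identity", time_term = "period",
                            covariates = FALSE)
  m0 <- predictive_margins(fit0, at = "period")
  cellmeans <- tapply(d$y, d$period, mean)
  expect_equal(m0$margin, as.numeric(cellmeans[m0$level]),
               tolerance = 1e-10)
  # with covariates the saturated-in-period structure is preserved loosely
  fit <- fit_symptom_model(d, "gaussian_identity", time_term = "period")
  m <- predictive_margins(fit, at = "period")
  expect_true(all(is.finite(m$margin)) && all(m$margin >= 0))
})
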