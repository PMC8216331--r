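test_that("self-reference detection follows the token rules", {
  expect_true(detect_self_reference("Ich fühle mich immer so energielos."))
  expect_false(detect_self_reference("Sie fühlt sich ständig energielos."))
  expect_true(detect_self_reference("Bro ich bin die Enttäuschung der Familie."))
  # token-level, never substring: "michel" must not trigger "mich"
  expect_false(detect_self_reference("Michel wirkt heute müde."))
  # case-insensitive; custom rules are honoured
  expect_true(detect_self_reference("MIR geht es schlecht."))
  rules <- self_reference_rules(pronouns = "meinerseits", verbs = character())
  expect_false(detect_self_reference("ich bin müde", rules))
  expect_true(detect_self_reference("meinerseits alles gut", rules))
})

test_that("ISO calendar weeks and period labels follow the German convention", {
  expect_equal(iso_week(as.Date("2020-01-01")), 1L)
  expect_equal(iso_week(as.Date("2019-12-30")), 1L)  # week 1 starts in Dec
  expect_equal(iso_week(as.Date("2020-03-22")), 12L) # contact ban start
  expect_equal(iso_week(as.Date("2020-07-30")), 31L)
  w <- study_window()
  expect_equal(as.character(label_periods(c(11, 12, 18, 19), w)),
               c("before", "during", "during", "after"))
  expect_error(label_periods(40, w), "outside")
  # edge weeks of the 2020 window are partial
  expect_equal(week_days_in_window(1, w), 5L)
  expect_equal(week_days_in_window(31, w), 4L)
  expect_equal(week_days_in_window(15, w), 7L)
})

test_that("the classification pipeline filters in fixed order with monotone counts", {
  lex <- tiny_lexicon()
  w <- study_window()
  recs <- tibble::tibble(
    text = c("RT @x: Ich bin so energielos",        # retweet (text prefix)
             "Ich bin so energielos",               # retained
             "Er ist so energielos",                # not self-referenced
             "Ich bin einfach nur gut drauf",       # no keyword
             "Ich bin so energielos"),              # outside window
    timestamp = c("2020-02-01", "2020-02-01", "2020-02-01", "2020-02-01",
                  "2021-02-01"),
    user_id = paste0("u", 1:5),
    is_retweet = c(FALSE, FALSE, FALSE, FALSE, FALSE))
  cl <- suppressMessages(classify_tweets(recs, lex, window = w))
  st <- attr(cl, "stage_counts")
  expect_equal(unname(st), c(5L, 4L, 3L, 2L, 1L))
  expect_true(all(diff(st) <= 0))
  expect_equal(cl$text, "Ich bin so energielos")
  expect_equal(cl$calendar_week, 5L)
  expect_true(all(cl$self_referenced))

  # an input of only retweets dies at stage 2
  rts <- tibble::tibble(text = rep("RT @x: Ich bin energielos", 3),
                        timestamp = "2020-02-01", user_id = "u",
                        is_retweet = TRUE)
  cl2 <- suppressMessages(classify_tweets(rts, lex, window = w))
  expect_equal(nrow(cl2), 0L)
  expect_equal(attr(cl2, "stage_counts")[["original"]], 0L)
  expect_equal(attr(cl2, "stage_counts")[["in_window"]], 3L)
})

test_that("malformed timestamps are rejected with a warning, not a crash", {
  lex <- tiny_lexicon()
  recs <- tibble::tibble(
    text = c("Ich bin energielos", "Ich bin energielos"),
    timestamp = c("not-a-date", "2020-02-01"),
    user_id = c("a", "b"), is_retweet = FALSE)
  expect_warning(
    cl <- suppressMessages(classify_tweets(recs, lex)),
    "malformed")
  expect_equal(nrow(cl), 1L)
})

test_that("classification is idempotent on its own output", {
  cfg <- quick_cfg(seed = 14L)
  lex <- tiny_lexicon()
  tw <- generate_tweets(cfg, lex)
  cl1 <- suppressMessages(classify_tweets(tw, lex, window = cfg$window))
  cl2 <- suppressMessages(classify_tweets(cl1, lex, window = cfg$window))
  expect_equal(nrow(cl2), nrow(cl1))
  expect_equal(cl2$text, cl1$text)
  expect_equal(cl2$symptoms, cl1$symptoms)
})

test_that("retention share tracks the configured self-reference rate", {
  cfg <- synth_config(n_respondents = 10L, n_users = 4000L, rng_seed = 31L,
                      self_reference_rate = 0.5, retweet_rate = 0)
  lex <- tiny_lexicon()
  tw <- generate_tweets(cfg, lex)
  cl <- suppressMessages(classify_tweets(tw, lex, window = cfg$window))
  share <- nrow(cl) / nrow(tw)
  expect_lt(abs(share - 0.5), 4 * sqrt(0.25 / nrow(tw)))
})

test_that("weekly aggregation divides by in-window days and conserves counts", {
  w <- study_window()
  # 70 fatigue tweets spread over the 7 days of week 10
  days <- iso_week_start(10, 2020) + rep(0:6, each = 10)
  cl <- tibble::tibble(
    text = "x", user_id = "u",
    symptoms = rep(list("fatigue_energy_loss"), 70),
    calendar_week = rep(10L, 70), timestamp = days)
  wk <- aggregate_weekly(cl, w)
  expect_equal(wk$value[wk$symptom == "fatigue_energy_loss" & wk$week == 10],
               10.0)
  expect_true(all(wk$value[wk$week != 10] == 0))
  expect_true(all(wk$partial_week == (wk$week %in% c(1L, 31L))))

  # empty input: an all-zero series over the whole window
  wk0 <- aggregate_weekly(cl[0, ], w)
  expect_equal(nrow(wk0), 5L * 31L)
  expect_true(all(wk0$value == 0))

  # conservation on generator output, including multi-symptom tweets
  cfg <- quick_cfg(seed = 2L)
  tw <- generate_tweets(cfg, tiny_lexicon())
  clg <- suppressMessages(classify_tweets(tw, tiny_lexicon(),
                                          window = cfg$window))
  wkg <- aggregate_weekly(clg, w)
  expect_equal(sum(wkg$n), sum(lengths(clg$symptoms)))
  expect_equal(sum(wkg$value * wkg$days), sum(lengths(clg$symptoms)))
})

test_that("rare-symptom exclusion uses a strict daily-mean threshold", {
  w <- study_window()
  total_days <- sum(week_days_in_window(w$weeks, w))
  mk <- function(sym, mean_per_day) {
    n <- round(mean_per_day * total_days)
    tibble::tibble(symptom = sym, week = w$weeks,
                   n = c(rep(n %/% 31, 30), n - 30 * (n %/% 31)),
                   days = week_days_in_window(w$weeks, w))
  }
  weekly <- dplyr::bind_rows(mk("fatigue_energy_loss", 12.0),
                             mk("worthlessness_guilt", 11.99))
  # exact boundary: 12.0/day retained, strictly below excluded
  weekly$n[weekly$symptom == "fatigue_energy_loss"] <-
    c(rep(82, 30), 12 * total_days - 30 * 82)
  ret <- suppressMessages(exclude_rare_symptoms(weekly, threshold = 12))
  means <- attr(ret, "daily_mean")
  expect_equal(means[["fatigue_energy_loss"]], 12.0)
  expect_lt(means[["worthlessness_guilt"]], 12)
  expect_true("fatigue_energy_loss" %in% ret)
  expect_equal(attr(ret, "excluded"), "worthlessness_guilt")
  # all symptoms at/above threshold: identity
  ret2 <- suppressMessages(exclude_rare_symptoms(
    mk("depressed_mood", 30), threshold = 12))
  expect_equal(as.character(ret2), "depressed_mood")
  expect_length(attr(ret2, "excluded"), 0L)
})

test_that("self-reference detection agrees with generator ground truth", {
  cfg <- quick_cfg(seed = 77L)
  tw <- generate_tweets(cfg, tiny_lexicon())
  originals <- !tw$is_retweet
  expect_equal(detect_self_reference(tw$text[originals]),
               tw$truth_self_ref[originals])
})
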