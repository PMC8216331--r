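#' Default self-reference rule configuration
#'
#' Token lists marking a German text as self-referenced: first-person
#' pronouns (including possessive inflections) and common first-person
#' verb forms. Matching is case-insensitive and token-level (never
#' substring), so "michel" does not trigger "mich".
#'
#' @param pronouns,verbs Character vectors overriding the defaults.
#' @return List of class `self_ref_rules`.
#' @export
self_reference_rules <- function(
    pronouns = c("ich", "mir", "mich",
                 "mein", "meine", "meiner", "meinem", "meinen", "meins",
                 "wir", "uns",
                 "unser", "unsere", "unserer", "unserem", "unseren"),
    verbs = c("bin", "habe", "hab", "fühle", "fuehle", "leide", "mag",
              "schaffe", "kann", "muss", "will", "denke", "weiß", "weiss")) {
  structure(list(pronouns = tolower(pronouns), verbs = tolower(verbs)),
            class = "self_ref_rules")
}

#' Detect whether a text is phrased in a self-referenced manner
#'
#' A symptom mention only counts as a self-report when the author applies
#' it to themselves; this is approximated by the presence of at least one
#' first-person pronoun or first-person verb-form token.
#'
#' @param text Character vector of texts.
#' @param rules A [self_reference_rules()] configuration.
#' @return Logical vector.
#' @examples
#' detect_self_reference("Ich fühle mich immer so energielos.")
#' detect_self_reference("Sie fühlt sich ständig energielos.")
#' @export
detect_self_reference <- function(text, rules = self_reference_rules()) {
  marks <- c(rules$pronouns, rules$verbs)
  vapply(tokenize_text(text),
         function(tok) any(tok %in% marks), logical(1L))
}

is_retweet_text <- function(text) grepl("^\\s*RT @", text)

#' Filter and classify a tweet stream
#'
#' Applies the fixed collection pipeline: (1) drop records with timestamps
#' outside the study window (malformed timestamps are rejected with a
#' warning, never a crash); (2) drop retweets (the `is_retweet` flag or a
#' leading `"RT @"` prefix; quoted tweets count as originals); (3) exact
#' keyword matching against the lexicon, dropping non-matching records;
#' (4) self-reference filtering. Assigns the ISO calendar week and reports
#' per-stage retention counts.
#'
#' @param records Tibble of tweet records (`text`, `timestamp`, `user_id`,
#'   optional `is_retweet`, `sex`, `age_group`, `region`).
#' @param lexicon A `symptom_lexicon`.
#' @param rules A [self_reference_rules()].
#' @param window A [study_window()].
#' @return Tibble of retained tweets with list-column `symptoms` (matched
#'   symptom sets), `self_referenced = TRUE`, and `calendar_week`; the
#'   per-stage counts are attached as attribute `"stage_counts"` and
#'   reported via `message()`.
#' @export
classify_tweets <- function(records, lexicon = default_lexicon(),
                            rules = self_reference_rules(),
                            window = study_window()) {
  if (nrow(lexicon) == 0L) stop("empty lexicon", call. = FALSE)
  stages <- c(input = nrow(records))

  ts <- if (inherits(records$timestamp, "Date")) records$timestamp
        else as.Date(as.character(records$timestamp), format = "%Y-%m-%d")
  bad <- is.na(ts)
  if (any(bad))
    warning(sum(bad), " record(s) with malformed timestamps rejected",
            call. = FALSE)
  in_win <- !bad & ts >= window$start & ts <= window$end
  records <- records[in_win, , drop = FALSE]
  records$timestamp <- ts[in_win]
  stages["in_window"] <- nrow(records)

  rt <- (if ("is_retweet" %in% names(records))
    records$is_retweet %in% TRUE else FALSE) |
    is_retweet_text(records$text)
  records <- records[!rt, , drop = FALSE]
  stages["original"] <- nrow(records)

  symptoms <- match_symptoms_batch(records$text, lexicon)
  has_kw <- lengths(symptoms) > 0L
  records <- records[has_kw, , drop = FALSE]
  symptoms <- symptoms[has_kw]
  stages["keyword_match"] <- nrow(records)

  self_ref <- detect_self_reference(records$text, rules)
  records <- records[self_ref, , drop = FALSE]
  symptoms <- symptoms[self_ref]
  stages["self_referenced"] <- nrow(records)

  records$symptoms <- symptoms
  records$self_referenced <- TRUE
  records$calendar_week <- iso_week(records$timestamp)

  message(paste(sprintf("%s: %d", names(stages), stages), collapse = " -> "))
  attr(records, "stage_counts") <- stages
  records
}

#' Aggregate classified tweets into weekly per-symptom series
#'
#' Weekly value = symptom tweet count that week divided by the number of
#' calendar days of that week inside the study window (edge weeks can be
#' partial and are flagged). A tweet matching several symptoms contributes
#' once to each matched series; weeks without tweets appear with value 0.
#'
#' @param classified Output of [classify_tweets()].
#' @param window A [study_window()].
#' @return Tidy tibble: `source` (`"twitter"`), `symptom`, `week`,
#'   `period`, `value` (mean tweets/day), `n` (tweet count), `days`,
#'   `partial_week`.
#' @export
aggregate_weekly <- function(classified, window = study_window()) {
  pairs <- tibble::tibble(
    symptom = as.character(unlist(classified$symptoms %||% list(),
                                  use.names = FALSE)),
    week = as.integer(rep(classified$calendar_week,
                          lengths(classified$symptoms)))
  )
  grid <- tidyr::expand_grid(symptom = phq_symptoms, week = window$weeks)
  counts <- dplyr::count(pairs, .data$symptom, .data$week, name = "n")
  out <- dplyr::left_join(grid, counts, by = c("symptom", "week"))
  out$n[is.na(out$n)] <- 0L
  out$days <- week_days_in_window(out$week, window)
  out$value <- ifelse(out$days > 0, out$n / out$days, NA_real_)
  out$period <- label_periods(out$week, window)
  out$partial_week <- out$days < 7L
  out$source <- "twitter"
  out[, c("source", "symptom", "week", "period", "value", "n", "days",
          "partial_week")]
}

#' Exclude symptoms with too few tweets per day
#'
#' A symptom whose mean daily tweet count over the whole window is
#' strictly below the threshold carries too little signal for temporal
#' modelling and is excluded (reported, never silent).
#'
#' @param weekly Tidy weekly series from [aggregate_weekly()].
#' @param threshold Minimum mean tweets/day. Default 12.
#' @return Character vector of retained symptoms; the excluded set and
#'   the per-symptom daily means are attached as attributes `"excluded"`
#'   and `"daily_mean"`.
#' @export
exclude_rare_symptoms <- function(weekly, threshold = 12) {
  if (threshold <= 0) abort_config("threshold", "must be positive")
  means <- vapply(split(weekly, weekly$symptom), function(d)
    sum(d$n) / sum(d$days), numeric(1L))
  retained <- names(means)[means >= threshold]
  excluded <- setdiff(names(means), retained)
  if (length(excluded))
    message("excluded (mean < ", threshold, " tweets/day): ",
            paste(sprintf("%s (%.1f/day)", excluded, means[excluded]),
                  collapse = ", "))
  structure(retained, excluded = excluded, daily_mean = means)
}
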