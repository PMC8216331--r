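#' Read and write tweet streams as JSON Lines
#'
#' One record per line, UTF-8. Required keys: `text`, `timestamp`
#' (ISO-8601 date), `user_id`; `is_retweet`, `sex`, `age_group`, `region`
#' are optional and default to `FALSE` / `"unknown"` / `NA` on read.
#'
#' @param records Tweet tibble (see [generate_tweets()]).
#' @param path File path.
#' @return `write_tweets_jsonl()` returns `path` invisibly;
#'   `read_tweets_jsonl()` a tibble.
#' @export
write_tweets_jsonl <- function(records, path) {
  df <- as.data.frame(records)
  df$timestamp <- format(as.Date(df$timestamp), "%Y-%m-%d")
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  jsonlite::stream_out(df, con, verbose = FALSE, auto_unbox = TRUE,
                       na = "null", digits = NA)
  invisible(path)
}

#' @rdname write_tweets_jsonl
#' @export
read_tweets_jsonl <- function(path) {
  con <- file(path, open = "r", encoding = "UTF-8")
  on.exit(close(con))
  df <- jsonlite::stream_in(con, verbose = FALSE)
  need <- setdiff(c("text", "timestamp", "user_id"), names(df))
  if (length(need))
    stop("JSONL tweet input lacks required key(s): ",
         paste(need, collapse = ", "), call. = FALSE)
  df$timestamp <- as.Date(df$timestamp)
  if (is.null(df$is_retweet)) df$is_retweet <- FALSE
  df$is_retweet[is.na(df$is_retweet)] <- FALSE
  if (is.null(df$sex)) df$sex <- "unknown"
  if (is.null(df$age_group)) df$age_group <- "unknown"
  if (is.null(df$region)) df$region <- NA_character_
  tibble::as_tibble(df)
}

#' Read and write survey cohorts as CSV
#'
#' Header columns: `id`, `week`, `sex`, `age_group`, `weight`,
#' `item_interest`, `item_mood`, `item_sleep`, `item_fatigue`,
#' `item_worth`.
#'
#' @param records Survey tibble (see [generate_survey()]).
#' @param path File path.
#' @export
write_survey_csv <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- setdiff(c("id", "week", "sex", "age_group", "weight",
                    unname(symptom_items)), names(df))
  if (length(need))
    stop("survey CSV lacks required column(s): ",
         paste(need, collapse = ", "), call. = FALSE)
  tibble::as_tibble(df)
}

#' Published sample-composition counts
#'
#' The study's printed sample-composition counts with denominators that
#' are themselves printed, so each percentage is pure arithmetic:
#' count / total. `recompute_composition()` recomputes each percentage
#' (rounded to one decimal) alongside the printed value. Survey-side
#' symptom and age-group percentages are *not* included here: they are
#' survey-weighted and do not recompute from the unweighted counts.
#'
#' @return A tibble with columns `quantity`, `count`, `total`,
#'   `printed_pct`, and (for `recompute_composition()`) `recomputed_pct`.
#' @export
sample_composition <- function() {
  tibble::tibble(
    quantity = c("survey_female", "twitter_female",
                 "twitter_worthlessness_share", "twitter_fatigue_share",
                 "twitter_age_10_17", "twitter_age_18_24",
                 "twitter_age_25_34", "twitter_age_35_49",
                 "twitter_age_50_plus"),
    count = c(4659, 74587, 5103, 31005, 11385, 51272, 11485, 9408, 5350),
    total = c(9011, 88900, 88900, 88900, 88900, 88900, 88900, 88900, 88900),
    printed_pct = c(51.7, 83.9, 5.7, 34.9, 12.8, 57.7, 12.9, 10.6, 6.0)
  )
}

#' @rdname sample_composition
#' @export
recompute_composition <- function() {
  d <- sample_composition()
  d$recomputed_pct <- round(100 * d$count / d$total, 1)
  d
}
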