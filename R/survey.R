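#' Dichotomize a graded PHQ item response
#'
#' Collapses the 0--3 frequency scale ("not at all" ... "nearly every
#' day") into not-at-all-affected (0) vs affected (1), the coding that
#' makes questionnaire frequencies comparable to keyword mention
#' frequencies.
#'
#' @param response Numeric vector of responses; values outside
#'   `{0,1,2,3}` (including `NA`) become `NA` and the count is reported.
#' @return Integer vector of 0/1/NA. Idempotent on already-binary input.
#' @examples
#' dichotomize(c(0, 1, 2, 3))
#' @export
dichotomize <- function(response) {
  response <- suppressWarnings(as.numeric(response))
  ok <- !is.na(response) & response %in% 0:3
  if (any(!ok))
    message(sum(!ok), " out-of-range or missing item response(s) set to NA")
  out <- rep(NA_integer_, length(response))
  out[ok] <- as.integer(response[ok] >= 1)
  out
}

#' Aggregate survey records into weighted weekly symptom proportions
#'
#' Weekly value per symptom = sum(weight * affected) / sum(weight) over
#' that week's respondents with a valid item response (available-case per
#' item, not listwise). Weeks without any valid respondent are flagged
#' missing (`NA`), never zero. Invariant to rescaling all weights by a
#' positive constant.
#'
#' @param records Survey tibble with columns `week`, `weight` and the
#'   five item columns (see [generate_survey()]).
#' @param window A [study_window()].
#' @return Tidy tibble: `source` (`"survey"`), `symptom`, `week`,
#'   `period`, `value` (weighted proportion in \[0,1\] or `NA`), `n`
#'   (respondents contributing).
#' @export
aggregate_weekly_weighted <- function(records, window = study_window()) {
  if (!"weight" %in% names(records) || any(records$weight <= 0, na.rm = TRUE))
    abort_config("weight", "positive survey weights are required")
  rows <- lapply(phq_symptoms, function(sym) {
    y <- dichotomize(records[[symptom_items[[sym]]]])
    ok <- !is.na(y)
    d <- tibble::tibble(week = records$week[ok], w = records$weight[ok],
                        y = y[ok])
    agg <- dplyr::summarise(
      dplyr::group_by(d, .data$week),
      value = sum(.data$w * .data$y) / sum(.data$w),
      n = dplyr::n(), .groups = "drop")
    out <- dplyr::left_join(tibble::tibble(week = window$weeks), agg,
                            by = "week")
    out$n[is.na(out$n)] <- 0L
    out$symptom <- sym
    out
  })
  out <- dplyr::bind_rows(rows)
  if (any(out$n == 0L))
    message(sum(out$n == 0L), " symptom-week(s) without respondents ",
            "flagged missing")
  out$period <- label_periods(out$week, window)
  out$source <- "survey"
  out[, c("source", "symptom", "week", "period", "value", "n")]
}
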