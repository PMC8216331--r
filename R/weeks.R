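#' ISO-8601 calendar week utilities
#'
#' German "Kalenderwoche" follows ISO 8601: weeks start on Monday and week 1
#' is the week containing January 4th. `iso_week()` returns the ISO week
#' number of a date; `iso_week_start()` the Monday starting a given ISO week
#' of a given year.
#'
#' @param date A `Date` vector (or something coercible by [as.Date()]).
#' @param week Integer ISO week number(s).
#' @param year Integer ISO year.
#' @return `iso_week()`: integer vector of week numbers; `iso_week_start()`:
#'   a `Date` vector of Mondays.
#' @examples
#' iso_week(as.Date("2020-03-22")) # start of the contact ban: week 12
#' @export
iso_week <- function(date) {
  date <- as.Date(date)
  if (length(date) == 0L) return(integer(0))
  # ISO week via the week's Thursday: avoids locale/strftime dependence
  wd <- (as.integer(format(date, "%w")) + 6L) %% 7L  # Monday = 0
  thursday <- date - wd + 3L
  jan1 <- as.Date(paste0(format(thursday, "%Y"), "-01-01"))
  as.integer((as.integer(thursday - jan1) %/% 7L) + 1L)
}

#' @rdname iso_week
#' @export
iso_week_start <- function(week, year) {
  jan4 <- as.Date(paste0(year, "-01-04"))
  wd <- (as.integer(format(jan4, "%w")) + 6L) %% 7L
  monday1 <- jan4 - wd
  monday1 + (as.integer(week) - 1L) * 7L
}

#' Number of days of an ISO week falling inside the study window
#'
#' Edge weeks of a study window can be partial (the window January 1 --
#' July 30, 2020 covers only 5 days of ISO week 1 and 4 days of week 31);
#' daily-average tweet frequencies divide by the days actually observed.
#'
#' @param week Integer ISO week number(s).
#' @param window A list with `start`, `end` (`Date`) and `year` (integer),
#'   as produced by [study_window()].
#' @return Integer vector: days of each week inside `[start, end]` (0 if
#'   disjoint).
#' @export
week_days_in_window <- function(week, window) {
  ws <- iso_week_start(week, window$year)
  we <- ws + 6L
  lo <- pmax(as.integer(ws), as.integer(window$start))
  hi <- pmin(as.integer(we), as.integer(window$end))
  pmax(hi - lo + 1L, 0L)
}

#' Define the study window
#'
#' @param start,end Window date bounds (inclusive).
#' @param weeks Integer vector of ISO weeks analysed (contiguous).
#' @param period_bounds Two integers `c(b1, b2)`: weeks `<= b1` are
#'   *before*, weeks `b1+1 .. b2` *during*, weeks `> b2` *after* the
#'   contact ban. Defaults to the first German social-contact ban of 2020
#'   (ban weeks 12--18).
#' @return A list with class `study_window`.
#' @export
study_window <- function(start = as.Date("2020-01-01"),
                         end = as.Date("2020-07-30"),
                         weeks = 1:31,
                         period_bounds = c(11L, 18L)) {
  start <- as.Date(start); end <- as.Date(end)
  if (end < start) abort_config("window", "end precedes start")
  weeks <- as.integer(weeks)
  if (any(diff(weeks) != 1L)) abort_config("weeks", "must be contiguous")
  pb <- as.integer(period_bounds)
  if (length(pb) != 2L || pb[1L] >= pb[2L])
    abort_config("period_bounds", "need two strictly increasing integers")
  if (pb[1L] < min(weeks) || pb[2L] >= max(weeks))
    abort_config("period_bounds", "must lie strictly inside the week range")
  structure(list(start = start, end = end, weeks = weeks,
                 year = as.integer(format(start, "%Y")),
                 period_bounds = pb),
            class = "study_window")
}

#' Label calendar weeks as before / during / after the contact ban
#'
#' @param week Integer ISO week number(s), inside the window's week range.
#' @param window A [study_window()].
#' @return Factor with levels `before`, `during`, `after` (in that order,
#'   so `before` is the reference level in model contrasts).
#' @examples
#' w <- study_window()
#' label_periods(c(11, 12, 18, 19), w)
#' @export
label_periods <- function(week, window = study_window()) {
  week <- as.integer(week)
  if (any(week < min(window$weeks) | week > max(window$weeks)))
    stop("week outside the study window", call. = FALSE)
  pb <- window$period_bounds
  lab <- ifelse(week <= pb[1L], "before",
                ifelse(week <= pb[2L], "during", "after"))
  factor(lab, levels = c("before", "during", "after"))
}
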