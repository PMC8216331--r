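#' Spearman rank-order correlation
#'
#' Tie-aware Spearman correlation: both vectors are transformed to
#' average ranks and their Pearson correlation is returned. Because the
#' two weekly series live on incomparable scales (weighted proportions vs
#' tweets/day) and their relation need not be linear, rank correlation is
#' the appropriate agreement measure; it is invariant under strictly
#' increasing transforms of either input. The p-value uses the t
#' approximation on n - 2 df by default; for n <= 8 an exact permutation
#' p-value (full enumeration of all n! orderings) is available.
#'
#' @param x,y Numeric vectors of equal length >= 3, no missing values
#'   (drop incomplete pairs upstream).
#' @param method `"t"` (default) or `"permutation"` (n <= 8 only).
#' @return List with class `spearman_result`: `rho`, `p_value`, `n`,
#'   `method`, `defined`. A constant input leaves `rho` undefined
#'   (`defined = FALSE`, `rho = NA`) rather than erroring.
#' @examples
#' spearman_rho(1:10, exp(1:10))   # rho = 1 under monotone transforms
#' @export
spearman_rho <- function(x, y, method = c("t", "permutation")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values: drop pairs upstream",
                                 call. = FALSE)
  out <- list(rho = NA_real_, p_value = NA_real_, n = n, method = method,
              defined = FALSE)
  class(out) <- "spearman_result"
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) return(out)

  rho_of <- function(a, b) {
    ra <- rank(a, ties.method = "average")
    rb <- rank(b, ties.method = "average")
    sum((ra - mean(ra)) * (rb - mean(rb))) /
      sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  }
  rho <- rho_of(x, y)
  out$rho <- rho
  out$defined <- TRUE
  if (method == "t") {
    if (abs(rho) >= 1) {
      out$p_value <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      out$p_value <- 2 * pt(-abs(tstat), df = n - 2)
    }
  } else {
    if (n > 8L)
      stop("exact permutation p-value is enumerated only for n <= 8",
           call. = FALSE)
    perms <- permutations_of(n)
    null_rho <- apply(perms, 1L, function(pm) rho_of(x, y[pm]))
    out$p_value <- mean(abs(null_rho) >= abs(rho) - 1e-12)
  }
  out
}

# all permutations of 1..n as a matrix (n! rows)
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (i in seq_len(n)) {
    rows <- nrow(sub)
    block <- cbind(rep(i, rows), matrix(setdiff(seq_len(n), i)[sub],
                                        rows, n - 1L))
    out[r + seq_len(rows), ] <- block
    r <- r + rows
  }
  out
}

#' @export
print.spearman_result <- function(x, ...) {
  if (x$defined)
    cat(sprintf("Spearman rho = %.4f (n = %d, p = %.4g, %s)\n",
                x$rho, x$n, x$p_value, x$method))
  else cat("Spearman rho undefined (constant input)\n")
  invisible(x)
}

#' Cross-source correspondence of weekly symptom trajectories
#'
#' For each symptom present in both inputs, the Spearman correlation of
#' the two sources' weekly values (typically model-smoothed weekly
#' margins) is computed at lag 0 — the headline agreement figure — and
#' over a scan of integer week lags. At lag `l` the twitter series is
#' shifted so that survey week `w` is paired with twitter week `w + l`;
#' a negative best lag therefore means the twitter signal leads the
#' survey signal. Lags whose overlap is shorter than 3 weeks are skipped
#' (reported via `message()`).
#'
#' @param survey_weekly,twitter_weekly Tidy tibbles with columns
#'   `symptom`, `week`, `value` (e.g. [weekly_margins()] output or the
#'   aggregation outputs). Missing-value weeks are dropped pairwise.
#' @param lags Integer lag range to scan. Default `-4:4`.
#' @return Tibble, one row per symptom: `symptom`, `rho`, `p_value`, `n`
#'   (overlap weeks at lag 0), `best_lag`, `rho_at_best`, plus the full
#'   lag profile in the list-column `lag_profile`.
#' @export
correlate_sources <- function(survey_weekly, twitter_weekly, lags = -4:4) {
  lags <- as.integer(lags)
  syms <- intersect(unique(survey_weekly$symptom),
                    unique(twitter_weekly$symptom))
  rows <- lapply(syms, function(sym) {
    s <- survey_weekly[survey_weekly$symptom == sym, c("week", "value")]
    t <- twitter_weekly[twitter_weekly$symptom == sym, c("week", "value")]
    profile <- lapply(lags, function(l) {
      m <- dplyr::inner_join(s, dplyr::mutate(t, week = .data$week - l),
                             by = "week", suffix = c("_s", "_t"))
      m <- m[complete.cases(m), , drop = FALSE]
      if (nrow(m) < 3L) {
        message(sprintf("%s: lag %+d skipped (overlap %d < 3 weeks)",
                        sym, l, nrow(m)))
        return(tibble::tibble(lag = l, rho = NA_real_,
                              p_value = NA_real_, n = nrow(m)))
      }
      r <- spearman_rho(m$value_s, m$value_t)
      tibble::tibble(lag = l, rho = r$rho, p_value = r$p_value, n = r$n)
    })
    profile <- dplyr::bind_rows(profile)
    at0 <- profile[profile$lag == 0L, , drop = FALSE]
    ok <- !is.na(profile$rho)
    best <- if (any(ok)) profile$lag[ok][which.max(profile$rho[ok])]
            else NA_integer_
    tibble::tibble(
      symptom = sym,
      rho = if (nrow(at0)) at0$rho else NA_real_,
      p_value = if (nrow(at0)) at0$p_value else NA_real_,
      n = if (nrow(at0)) at0$n else 0L,
      best_lag = best,
      rho_at_best = if (any(ok)) max(profile$rho[ok]) else NA_real_,
      lag_profile = list(profile)
    )
  })
  dplyr::bind_rows(rows)
}
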