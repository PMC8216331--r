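#' Build per-symptom model data for the two sources
#'
#' `survey_model_data()` returns one row per respondent with a valid item
#' response: dichotomized outcome `y`, `week`, `period`, demographic
#' covariates with the reference coding used throughout (sex reference
#' `male`, youngest age group first, period reference `before`) and the
#' survey `weight`. `twitter_model_data()` returns one row per calendar
#' week x sex x age-group cell with `y` = symptom tweets per day in that
#' cell (zero-filled grid), optionally volume-weighted.
#'
#' @param records Survey records (see [generate_survey()]).
#' @param classified Classified tweets from [classify_tweets()].
#' @param symptom One of [phq_symptoms].
#' @param window A [study_window()].
#' @param volume_weights If `TRUE`, weight twitter cells by their tweet
#'   count (+1); default unweighted.
#' @return A tibble with columns `y`, `week`, `period`, `sex`,
#'   `age_group`, `weight`.
#' @export
survey_model_data <- function(records, symptom, window = study_window()) {
  y <- dichotomize(records[[symptom_items[[symptom]]]])
  ok <- !is.na(y) & records$week %in% window$weeks
  tibble::tibble(
    y = y[ok],
    week = as.integer(records$week[ok]),
    period = label_periods(records$week[ok], window),
    sex = factor(records$sex[ok], levels = c("male", "female")),
    age_group = factor(records$age_group[ok],
                       levels = intersect(c("10-17", "15-17", "18-24",
                                            "25-34", "35-49", "50+"),
                                          unique(records$age_group[ok]))),
    weight = records$weight[ok]
  )
}

#' @rdname survey_model_data
#' @export
twitter_model_data <- function(classified, symptom, window = study_window(),
                               volume_weights = FALSE) {
  keep <- vapply(classified$symptoms, function(s) symptom %in% s, logical(1L))
  d <- classified[keep, , drop = FALSE]
  sexes <- sort(unique(d$sex))
  ages <- intersect(c("10-17", "15-17", "18-24", "25-34", "35-49", "50+",
                      "unknown"), unique(d$age_group))
  grid <- tidyr::expand_grid(week = window$weeks, sex = sexes,
                             age_group = ages)
  counts <- dplyr::count(
    tibble::tibble(week = d$calendar_week, sex = d$sex,
                   age_group = d$age_group),
    .data$week, .data$sex, .data$age_group, name = "n")
  out <- dplyr::left_join(grid, counts, by = c("week", "sex", "age_group"))
  out$n[is.na(out$n)] <- 0L
  days <- week_days_in_window(out$week, window)
  tibble::tibble(
    y = out$n / days,
    week = as.integer(out$week),
    period = label_periods(out$week, window),
    sex = factor(out$sex, levels = c("male", "female",
                                     setdiff(sexes, c("male", "female")))),
    age_group = factor(out$age_group, levels = ages),
    weight = if (volume_weights) out$n + 1 else rep(1, nrow(out))
  )
}

#' Append centered polynomial time terms to a model data frame
#'
#' Adds centered powers 1..`degree` of `week - center` as columns
#' `week_c1` ... Centering is for numerical conditioning only; fitted
#' values and margins are invariant to the choice of center.
#'
#' @param data Model data with a numeric `week` column.
#' @param center Centering constant; defaults to the mean observed week.
#' @param degree Polynomial degree (default 4).
#' @return `data` with the power columns added and the center stored in
#'   attribute `"poly_center"`.
#' @export
add_polynomial_time <- function(data, center = NULL, degree = 4L) {
  if (length(unique(data$week)) < degree + 1L)
    stop(sprintf(
      "only %d distinct weeks: a degree-%d polynomial in week is unidentifiable",
      length(unique(data$week)), degree), call. = FALSE)
  center <- center %||% mean(data$week)
  for (p in seq_len(degree))
    data[[paste0("week_c", p)]] <- (data$week - center)^p
  attr(data, "poly_center") <- center
  data
}

#' Fit a covariate-adjusted symptom regression
#'
#' The shared fitting surface for both sources: a weighted logistic
#' regression (survey: binary affected outcome, quasi-binomial IRLS so
#' non-integer survey weights are handled) or a weighted linear
#' regression (twitter: tweets/day outcome). Covariates are sex,
#' age group and their interaction (treatment coding; references: male,
#' youngest age group, period *before*). The time term is `"none"`
#' (covariates only), `"poly4"` (fourth-degree centered polynomial in
#' calendar week, smoothing weekly fluctuation) or `"period"` (the
#' three-level contact-ban factor). Covariance is heteroskedasticity-
#' robust (HC1 sandwich) by default.
#'
#' @param data Model data from [survey_model_data()] /
#'   [twitter_model_data()] (columns `y`, `week`, `period`, `sex`,
#'   `age_group`, `weight`).
#' @param family `"binomial_logit"` or `"gaussian_identity"`.
#' @param time_term `"none"`, `"poly4"` or `"period"`.
#' @param covariates Include sex * age_group controls? Default `TRUE`.
#' @param robust Use HC1 sandwich covariance (default) or the
#'   model-based one.
#' @param epsilon,maxit IRLS convergence tolerance (relative deviance
#'   change) and iteration cap.
#' @return Object of class `phq_fit`: the glm fit plus coefficient
#'   vector, robust covariance, convergence and separation flags, the
#'   estimation data and the polynomial center. Non-convergence and
#'   separation are flagged, never silent; a rank-deficient design is an
#'   error naming the aliased columns.
#' @export
fit_symptom_model <- function(data,
                              family = c("binomial_logit",
                                         "gaussian_identity"),
                              time_term = c("none", "poly4", "period"),
                              covariates = TRUE,
                              robust = TRUE,
                              epsilon = 1e-8, maxit = 100L) {
  family <- match.arg(family)
  time_term <- match.arg(time_term)
  rhs <- if (covariates) "sex * age_group" else "1"
  if (time_term == "poly4") {
    data <- add_polynomial_time(data)
    rhs <- paste(rhs, "+ week_c1 + week_c2 + week_c3 + week_c4")
  } else if (time_term == "period") {
    data$period <- factor(as.character(data$period),
                          levels = c("before", "during", "after"))
    rhs <- paste(rhs, "+ period")
  }
  fam <- if (family == "binomial_logit") quasibinomial("logit")
         else gaussian("identity")

  separation <- FALSE
  fit <- withCallingHandlers(
    glm(stats::as.formula(paste("y ~", rhs)), data = data, weights = weight,
        family = fam, control = glm.control(epsilon = epsilon,
                                            maxit = maxit)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })

  if (family == "binomial_logit" &&
      any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8))
    separation <- TRUE
  if (anyNA(coef(fit)))
    stop("rank-deficient design; aliased columns: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  if (!fit$converged)
    warning("IRLS did not converge within ", maxit, " iterations",
            call. = FALSE)
  if (separation)
    warning("possible separation: fitted probabilities at 0/1",
            call. = FALSE)

  V <- if (robust) sandwich::vcovHC(fit, type = "HC1") else vcov(fit)
  structure(list(
    model = fit, family = family, time_term = time_term,
    coefficients = coef(fit), vcov = V,
    converged = fit$converged, separation = separation,
    n = nrow(data), data = data,
    poly_center = attr(data, "poly_center")
  ), class = "phq_fit")
}

#' @export
coef.phq_fit <- function(object, ...) object$coefficients

#' @export
vcov.phq_fit <- function(object, ...) object$vcov

#' @export
print.phq_fit <- function(x, ...) {
  cat(sprintf("<phq_fit: %s, time term %s, n = %d%s>\n", x$family,
              x$time_term, x$n,
              if (x$converged) "" else ", NOT CONVERGED"))
  print(round(x$coefficients, 4))
  invisible(x)
}

# design matrix for (possibly counterfactual) newdata, honouring the
# fitted factor levels and contrasts
fit_design <- function(fit, newdata) {
  tt <- stats::delete.response(stats::terms(fit$model))
  mf <- stats::model.frame(tt, newdata, xlev = fit$model$xlevels)
  model.matrix(tt, mf, contrasts.arg = fit$model$contrasts)
}

# margin + delta-method gradient at one counterfactual setting
margin_at <- function(fit, newdata) {
  X <- fit_design(fit, newdata)
  beta <- fit$coefficients
  eta <- drop(X %*% beta)
  w <- fit$data$weight
  if (fit$family == "binomial_logit") {
    mu <- plogis(eta)
    dmu <- mu * (1 - mu)
  } else {
    mu <- eta
    dmu <- rep(1, length(eta))
  }
  margin <- weighted.mean(mu, w)
  grad <- colSums(w * dmu * X) / sum(w)
  list(margin = margin, grad = grad)
}

counterfactual <- function(fit, at_name, level) {
  nd <- fit$data
  if (at_name == "period") {
    nd$period <- factor(level, levels = levels(fit$data$period))
  } else {
    nd$week <- as.numeric(level)
    if (fit$time_term == "poly4")
      for (p in 1:4)
        nd[[paste0("week_c", p)]] <- (nd$week - fit$poly_center)^p
  }
  nd
}

#' Predictive margins of a fitted symptom model
#'
#' Observed-covariate ("predictive margin") averaging: the focal time
#' variable is set to each requested level for *every* observation, the
#' model response is predicted, and its weighted mean over the estimation
#' sample is reported. Standard errors come from the delta method applied
#' to the averaged prediction with the fit's (robust) coefficient
#' covariance; intervals are normal-based 95% CIs. For survey fits
#' margins are probabilities; for twitter fits, tweets/day.
#'
#' @param fit A `phq_fit`.
#' @param at Either `"period"` (margins at before/during/after; requires
#'   `time_term = "period"`) or a numeric vector of calendar weeks
#'   (requires `time_term = "poly4"` or `"none"`).
#' @param level Confidence level. Default 0.95.
#' @return Tibble: `level`, `margin`, `se`, `ci_low`, `ci_high`, with the
#'   per-level gradient matrix attached as attribute `"gradients"` (used
#'   for contrasts).
#' @export
predictive_margins <- function(fit, at = "period", level = 0.95) {
  stopifnot(inherits(fit, "phq_fit"))
  if (!fit$converged)
    stop("refusing margins from a non-converged fit", call. = FALSE)
  if (identical(at, "period")) {
    if (fit$time_term != "period")
      stop("model has no period term", call. = FALSE)
    levels_at <- levels(fit$data$period)
    at_name <- "period"
  } else {
    if (fit$time_term == "period")
      stop("week margins need a poly4 or covariate-only model", call. = FALSE)
    levels_at <- as.numeric(at)
    at_name <- "week"
  }
  res <- lapply(levels_at, function(lv)
    margin_at(fit, counterfactual(fit, at_name, lv)))
  margins <- vapply(res, `[[`, numeric(1L), "margin")
  G <- t(vapply(res, `[[`, numeric(length(fit$coefficients)), "grad"))
  se <- sqrt(pmax(rowSums((G %*% fit$vcov) * G), 0))
  z <- qnorm(1 - (1 - level) / 2)
  out <- tibble::tibble(level = levels_at, margin = margins, se = se,
                        ci_low = margins - z * se,
                        ci_high = margins + z * se)
  attr(out, "gradients") <- G
  out
}

#' Joint Wald test of the contact-ban period term
#'
#' Tests both period coefficients (during, after vs before) jointly with
#' the fit's robust covariance: the quadratic form
#' \eqn{b^\top V_b^{-1} b}. With a design/cluster degrees-of-freedom
#' argument `df2` the statistic is reported as a design-adjusted F on
#' (2, `df2`) df; otherwise as a large-sample chi-squared on 2 df.
#'
#' @param fit A `phq_fit` with `time_term = "period"`.
#' @param df2 Optional denominator df (e.g. number of design clusters
#'   minus one) for the small-sample F adjustment.
#' @return Tibble: `contrast`, `statistic`, `df1`, `df2`, `p_value`.
#' @export
wald_period_test <- function(fit, df2 = NULL) {
  stopifnot(inherits(fit, "phq_fit"))
  idx <- grep("^period", names(fit$coefficients))
  if (length(idx) == 0L) stop("model has no period term", call. = FALSE)
  b <- fit$coefficients[idx]
  V <- fit$vcov[idx, idx, drop = FALSE]
  W <- drop(t(b) %*% solve(V, b))
  q <- length(idx)
  if (is.null(df2)) {
    tibble::tibble(contrast = "period (joint)", statistic = W,
                   df1 = q, df2 = NA_real_,
                   p_value = pchisq(W, df = q, lower.tail = FALSE))
  } else {
    tibble::tibble(contrast = "period (joint)", statistic = W / q,
                   df1 = q, df2 = df2,
                   p_value = pf(W / q, q, df2, lower.tail = FALSE))
  }
}

#' Pairwise period contrasts on the margin scale
#'
#' Differences of predictive margins between contact-ban periods, with
#' delta-method standard errors that account for the covariance between
#' the two margins (both are functions of the same coefficient vector).
#' Normal-based z tests; no multiplicity correction is applied, matching
#' the per-comparison presentation of period contrasts.
#'
#' @param fit A `phq_fit` with `time_term = "period"`.
#' @param pairs List of 2-element character vectors of period levels;
#'   defaults to the three ordered pairs.
#' @return Tibble: `contrast`, `estimate`, `se`, `statistic` (z),
#'   `p_value`. A level contrasted with itself yields statistic 0 and
#'   p = 1.
#' @export
pairwise_contrasts <- function(fit,
                               pairs = list(c("before", "during"),
                                            c("before", "after"),
                                            c("during", "after"))) {
  m <- predictive_margins(fit, at = "period")
  G <- attr(m, "gradients")
  rows <- lapply(pairs, function(pr) {
    i <- match(pr[1L], m$level); j <- match(pr[2L], m$level)
    if (anyNA(c(i, j))) stop("unknown period level in contrast", call. = FALSE)
    est <- m$margin[i] - m$margin[j]
    g <- G[i, ] - G[j, ]
    se <- sqrt(max(drop(t(g) %*% fit$vcov %*% g), 0))
    z <- if (se > 0) est / se else 0
    tibble::tibble(contrast = paste(pr[1L], "vs", pr[2L]),
                   estimate = est, se = se, statistic = z,
                   p_value = if (se > 0) 2 * pnorm(-abs(z)) else 1)
  })
  dplyr::bind_rows(rows)
}
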