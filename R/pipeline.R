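#' Assemble and validate a pipeline run configuration
#'
#' A run configuration bundles the synthetic-generator settings, lexicon
#' parameters, self-reference rules, model options and output location of
#' an end-to-end run. `read_run_config()` loads it from YAML (keys mirror
#' the argument names; unknown keys are an error); values supplied
#' directly override the file.
#'
#' @param synth A [synth_config()]; its `rng_seed` seeds the whole run.
#' @param tau,k Lexicon expansion threshold and neighbour budget.
#' @param seed_table,related_words Seed/related word tables (named lists).
#' @param deny,allow Manual curation lists passed to [expand_lexicon()].
#' @param rules A [self_reference_rules()].
#' @param exclusion_threshold Minimum mean tweets/day for a symptom to be
#'   modelled. Default 12.
#' @param volume_weights Weight twitter model cells by tweet volume?
#' @param lags Lag range for the correspondence scan.
#' @param out_dir Optional output directory for stage artifacts.
#' @return List of class `run_config`.
#' @export
run_config <- function(synth = synth_config(),
                       tau = 0.4, k = 25L,
                       seed_table = default_seed_table(),
                       related_words = default_related_words(),
                       deny = character(), allow = list(),
                       rules = self_reference_rules(),
                       exclusion_threshold = 12,
                       volume_weights = FALSE,
                       lags = -4:4,
                       out_dir = NULL) {
  stopifnot(inherits(synth, "synth_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  structure(list(synth = synth, tau = tau, k = k,
                 seed_table = seed_table, related_words = related_words,
                 deny = deny, allow = allow, rules = rules,
                 exclusion_threshold = exclusion_threshold,
                 volume_weights = volume_weights, lags = lags,
                 out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param path Path to a YAML file.
#' @param ... Overrides applied on top of the file's keys.
#' @export
read_run_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  raw <- utils::modifyList(raw, list(...))
  synth_keys <- intersect(names(raw), names(formals(synth_config)))
  other_keys <- setdiff(names(raw), synth_keys)
  known <- setdiff(names(formals(run_config)), "synth")
  bad <- setdiff(other_keys, known)
  if (length(bad))
    abort_config(bad[1L], "unknown configuration key")
  if ("rng_seed" %in% names(raw) || length(synth_keys)) {
    if (!"rng_seed" %in% synth_keys)
      abort_config("rng_seed", "a seed is mandatory for synthetic runs")
  }
  synth <- do.call(synth_config, raw[synth_keys])
  do.call(run_config, c(list(synth = synth), raw[other_keys]))
}

#' Smoothed weekly predictive margins for one source
#'
#' Fits the fourth-degree polynomial model for each requested symptom and
#' returns its weekly predictive margins — the smoothed trajectories the
#' cross-source correlation is computed on.
#'
#' @param data_fn Function `symptom -> model data` (closure over the
#'   records).
#' @param symptoms Symptoms to smooth.
#' @param family Model family for the source.
#' @param window A [study_window()].
#' @return Tidy tibble: `symptom`, `week`, `value` (weekly margin), `se`.
#' @export
weekly_margins <- function(data_fn, symptoms, family, window = study_window()) {
  rows <- lapply(symptoms, function(sym) {
    fit <- fit_symptom_model(data_fn(sym), family = family,
                             time_term = "poly4")
    m <- predictive_margins(fit, at = window$weeks)
    tibble::tibble(symptom = sym, week = as.integer(m$level),
                   value = m$margin, se = m$se)
  })
  dplyr::bind_rows(rows)
}

#' Run the full dual-source pipeline on synthetic data
#'
#' Executes every stage in order — lexicon construction (seeds, synthetic
#' enrichment corpus, embedding, expansion), synthetic survey and tweet
#' generation, tweet filtering/classification, weekly aggregation of both
#' sources, rare-symptom exclusion, the six regression models per
#' retained symptom (covariate-only, polynomial-smoothed and period
#' models for each source) with period margins, Wald tests and pairwise
#' contrasts, and the cross-source Spearman correspondence with lag scan.
#' Identical configuration and seed give an identical report; every
#' filtering step's effect appears in the report (no silent data loss).
#'
#' @param config A [run_config()].
#' @return List of class `run_report`: `stage_counts`, `excluded`
#'   (symptoms below the tweets/day threshold), `lexicon`, `margins`
#'   (period-level margins, both sources), `wald` (joint tests),
#'   `contrasts` (pairwise period comparisons), `weekly` (raw weekly
#'   series), `smoothed` (poly4 weekly margins), `correspondence`,
#'   `convergence`. If `config$out_dir` is set, stage outputs are also
#'   written there (JSONL/CSV/JSON plus a manifest).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  window <- config$synth$window

  # --- lexicon stage -------------------------------------------------
  seeds <- build_seed_sets(config$seed_table)
  corpus <- generate_corpus(config$synth, config$seed_table,
                            config$related_words)
  phrases <- grep(" ", unlist(c(config$seed_table, config$related_words),
                              use.names = FALSE), value = TRUE)
  space <- train_embedding(corpus, window = 4L, dim = 30L, min_count = 2L,
                           phrases = phrases)
  lexicon <- expand_lexicon(seeds, space, tau = config$tau, k = config$k,
                            deny = config$deny, allow = config$allow)

  # --- synthetic data stage -----------------------------------------
  survey <- generate_survey(config$synth)
  tweets <- generate_tweets(config$synth, lexicon)

  # --- tweets stage --------------------------------------------------
  classified <- classify_tweets(tweets, lexicon, config$rules, window)
  twitter_weekly <- aggregate_weekly(classified, window)
  retained <- exclude_rare_symptoms(twitter_weekly,
                                    config$exclusion_threshold)
  excluded <- attr(retained, "excluded")

  # --- survey stage --------------------------------------------------
  survey_weekly <- aggregate_weekly_weighted(survey, window)

  # --- models stage --------------------------------------------------
  sdata <- function(sym) survey_model_data(survey, sym, window)
  tdata <- function(sym) twitter_model_data(classified, sym, window,
                                            config$volume_weights)
  margins <- list(); wald <- list(); contrasts <- list(); conv <- list()
  for (sym in retained) {
    for (src in c("survey", "twitter")) {
      fam <- if (src == "survey") "binomial_logit" else "gaussian_identity"
      dat <- if (src == "survey") sdata(sym) else tdata(sym)
      fit <- fit_symptom_model(dat, family = fam, time_term = "period")
      conv[[paste(src, sym)]] <- fit$converged && !fit$separation
      m <- predictive_margins(fit, at = "period")
      margins[[length(margins) + 1L]] <-
        tibble::tibble(source = src, symptom = sym, period = m$level,
                       margin = m$margin, ci_low = m$ci_low,
                       ci_high = m$ci_high)
      w <- wald_period_test(fit)
      wald[[length(wald) + 1L]] <-
        tibble::tibble(source = src, symptom = sym,
                       statistic = w$statistic, p_value = w$p_value)
      ct <- pairwise_contrasts(fit)
      contrasts[[length(contrasts) + 1L]] <-
        tibble::tibble(source = src, symptom = sym, contrast = ct$contrast,
                       estimate = ct$estimate, p_value = ct$p_value)
    }
  }

  # --- correspondence stage -----------------------------------------
  smoothed <- NULL; corr <- NULL
  if (length(retained) == 0L) {
    message("all symptoms excluded; correspondence stage skipped")
  } else {
    sm_s <- weekly_margins(sdata, retained, "binomial_logit", window)
    sm_t <- weekly_margins(tdata, retained, "gaussian_identity", window)
    smoothed <- dplyr::bind_rows(
      dplyr::mutate(sm_s, source = "survey"),
      dplyr::mutate(sm_t, source = "twitter"))
    corr <- correlate_sources(sm_s, sm_t, lags = config$lags)
  }

  report <- structure(list(
    stage_counts = attr(classified, "stage_counts"),
    excluded = excluded,
    retained = as.character(retained),
    lexicon = lexicon,
    margins = dplyr::bind_rows(margins),
    wald = dplyr::bind_rows(wald),
    contrasts = dplyr::bind_rows(contrasts),
    weekly = dplyr::bind_rows(twitter_weekly[
      , c("source", "symptom", "week", "period", "value")],
      survey_weekly[, c("source", "symptom", "week", "period", "value")]),
    smoothed = smoothed,
    correspondence = corr,
    convergence = unlist(conv),
    rng_seed = config$synth$rng_seed
  ), class = "run_report")

  if (!is.null(config$out_dir)) write_run_outputs(report, survey, tweets,
                                                  config$out_dir)
  report
}

write_run_outputs <- function(report, survey, tweets, out_dir) {
  paths <- c(
    tweets = file.path(out_dir, "tweets.jsonl"),
    survey = file.path(out_dir, "survey.csv"),
    lexicon = file.path(out_dir, "lexicon.json"),
    weekly = file.path(out_dir, "weekly_series.csv"),
    margins = file.path(out_dir, "period_margins.csv"),
    contrasts = file.path(out_dir, "period_pvalues.csv"),
    correspondence = file.path(out_dir, "correspondence.csv"),
    smoothed = file.path(out_dir, "smoothed_margins.csv"),
    report = file.path(out_dir, "run_report.json")
  )
  write_tweets_jsonl(tweets, paths["tweets"])
  write_survey_csv(survey, paths["survey"])
  write_lexicon_json(report$lexicon, paths["lexicon"])
  utils::write.csv(report$weekly, paths["weekly"], row.names = FALSE)
  utils::write.csv(report$margins, paths["margins"], row.names = FALSE)
  utils::write.csv(report$contrasts, paths["contrasts"], row.names = FALSE)
  if (!is.null(report$correspondence))
    utils::write.csv(
      report$correspondence[, c("symptom", "rho", "p_value", "n", "best_lag")],
      paths["correspondence"], row.names = FALSE)
  if (!is.null(report$smoothed))
    utils::write.csv(report$smoothed, paths["smoothed"], row.names = FALSE)
  jsonlite::write_json(
    list(rng_seed = report$rng_seed,
         stage_counts = as.list(report$stage_counts),
         excluded = report$excluded, retained = report$retained,
         convergence = as.list(report$convergence),
         correspondence = if (!is.null(report$correspondence))
           report$correspondence[, c("symptom", "rho", "p_value",
                                     "best_lag")]),
    paths["report"], auto_unbox = TRUE, digits = NA, pretty = TRUE,
    na = "null")
  writeLines(paste(names(paths), unname(paths), sep = "\t"),
             file.path(out_dir, "MANIFEST.tsv"))
  invisible(paths)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n  stages: ",
      paste(sprintf("%s=%d", names(x$stage_counts), x$stage_counts),
            collapse = ", "), "\n", sep = "")
  cat("  retained symptoms: ", paste(x$retained, collapse = ", "), "\n")
  if (length(x$excluded))
    cat("  excluded: ", paste(x$excluded, collapse = ", "), "\n")
  if (!is.null(x$correspondence)) {
    cat("  correspondence (lag 0):\n")
    print(as.data.frame(
      x$correspondence[, c("symptom", "rho", "p_value", "best_lag")]),
      row.names = FALSE)
  }
  invisible(x)
}
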