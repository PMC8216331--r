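# Fit the six models per retained symptom: weighted logistic (survey) and
# linear (twitter) regressions with sex, age group and their interaction
# as controls, plus either the three-level contact-ban period or a
# fourth-degree polynomial in calendar week. Report period-level
# predictive margins, joint Wald tests and pairwise period contrasts.
source("analysis/00_common.R")

window <- study_cfg()$window
lexicon <- read_lexicon_json(file.path(RESULTS_DIR, "lexicon.json"))
tweets <- read_tweets_jsonl(file.path(RESULTS_DIR, "tweets.jsonl"))
survey <- read_survey_csv(file.path(RESULTS_DIR, "survey.csv"))
retained <- readLines(file.path(RESULTS_DIR, "retained_symptoms.txt"))
classified <- suppressMessages(classify_tweets(tweets, lexicon,
                                               window = window))

margins <- list(); pvals <- list()
for (sym in retained) {
  for (src in c("survey", "twitter")) {
    fam <- if (src == "survey") "binomial_logit" else "gaussian_identity"
    dat <- if (src == "survey") survey_model_data(survey, sym, window)
           else twitter_model_data(classified, sym, window)
    fit <- fit_symptom_model(dat, family = fam, time_term = "period")
    m <- predictive_margins(fit, at = "period")
    margins[[length(margins) + 1L]] <- data.frame(
      source = src, symptom = sym, period = m$level, margin = m$margin,
      ci_low = m$ci_low, ci_high = m$ci_high)
    w <- wald_period_test(fit)
    ct <- pairwise_contrasts(fit)
    pvals[[length(pvals) + 1L]] <- data.frame(
      source = src, symptom = sym,
      contrast = c(w$contrast, ct$contrast),
      p_value = c(w$p_value, ct$p_value))
  }
}
margins <- do.call(rbind, margins)
pvals <- do.call(rbind, pvals)

cat("Period margins (survey = probability, twitter = tweets/day):\n")
print(margins[margins$symptom == "fatigue_energy_loss", ],
      row.names = FALSE, digits = 3)
cat("\nPeriod comparison p-values for fatigue/energy loss:\n")
print(pvals[pvals$symptom == "fatigue_energy_loss", ],
      row.names = FALSE, digits = 3)

write.csv(margins, file.path(RESULTS_DIR, "period_margins.csv"),
          row.names = FALSE)
write.csv(pvals, file.path(RESULTS_DIR, "period_pvalues.csv"),
          row.names = FALSE)
cat("-> period_margins.csv, period_pvalues.csv\n")
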