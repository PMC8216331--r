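# Smooth both sources' weekly trajectories with the polynomial models and
# quantify cross-source agreement per symptom: Spearman rho at lag 0 plus
# an exploratory integer-week lag scan (negative best lag = the twitter
# signal leads the survey signal).
source("analysis/00_common.R")

window <- study_cfg()$window
lexicon <- read_lexicon_json(file.path(RESULTS_DIR, "lexicon.json"))
tweets <- read_tweets_jsonl(file.path(RESULTS_DIR, "tweets.jsonl"))
survey <- read_survey_csv(file.path(RESULTS_DIR, "survey.csv"))
retained <- readLines(file.path(RESULTS_DIR, "retained_symptoms.txt"))
classified <- suppressMessages(classify_tweets(tweets, lexicon,
                                               window = window))

sm_survey <- weekly_margins(
  function(sym) survey_model_data(survey, sym, window),
  retained, "binomial_logit", window)
sm_twitter <- weekly_margins(
  function(sym) twitter_model_data(classified, sym, window),
  retained, "gaussian_identity", window)

corr <- correlate_sources(sm_survey, sm_twitter, lags = -4:4)
cat("Cross-source Spearman correlation of smoothed weekly margins:\n")
print(as.data.frame(corr[, c("symptom", "rho", "p_value", "n",
                             "best_lag", "rho_at_best")]),
      row.names = FALSE, digits = 3)

write.csv(corr[, c("symptom", "rho", "p_value", "n", "best_lag")],
          file.path(RESULTS_DIR, "correspondence.csv"), row.names = FALSE)

# long week x symptom table of smoothed margins, heatmap-ready
sm_survey$source <- "survey"; sm_twitter$source <- "twitter"
smoothed <- rbind(sm_survey, sm_twitter)
write.csv(smoothed[, c("source", "symptom", "week", "value", "se")],
          file.path(RESULTS_DIR, "smoothed_margins.csv"),
          row.names = FALSE)
cat("-> correspondence.csv, smoothed_margins.csv\n")
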