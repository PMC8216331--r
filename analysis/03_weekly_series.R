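# Filter and classify the tweet stream (retweet removal, exact keyword
# match, self-reference filter), aggregate both sources to weekly
# per-symptom series, and apply the tweets/day exclusion rule.
source("analysis/00_common.R")

window <- study_cfg()$window
lexicon <- read_lexicon_json(file.path(RESULTS_DIR, "lexicon.json"))
tweets <- read_tweets_jsonl(file.path(RESULTS_DIR, "tweets.jsonl"))
survey <- read_survey_csv(file.path(RESULTS_DIR, "survey.csv"))

classified <- classify_tweets(tweets, lexicon, window = window)
st <- attr(classified, "stage_counts")
cat("Filter retention: ",
    paste(sprintf("%s=%d", names(st), st), collapse = " -> "), "\n")

twitter_weekly <- aggregate_weekly(classified, window)
retained <- exclude_rare_symptoms(twitter_weekly, threshold = 12)
cat("Retained symptoms (>= 12 tweets/day):",
    paste(retained, collapse = ", "), "\n")
cat("Mean tweets/day:\n")
print(round(attr(retained, "daily_mean"), 1))

survey_weekly <- aggregate_weekly_weighted(survey, window)

weekly <- rbind(
  twitter_weekly[, c("source", "symptom", "week", "period", "value")],
  survey_weekly[, c("source", "symptom", "week", "period", "value")])
write.csv(weekly, file.path(RESULTS_DIR, "weekly_series.csv"),
          row.names = FALSE)
writeLines(as.character(retained),
           file.path(RESULTS_DIR, "retained_symptoms.txt"))
cat("-> weekly_series.csv, retained_symptoms.txt\n")
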