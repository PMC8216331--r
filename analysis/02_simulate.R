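# Generate the synthetic study data: a survey cohort shaped like the
# national health-survey subsample (n = 9011, 51.7% female, 50+ modal)
# and a tweet stream shaped like the keyword-collected corpus (~87k
# tweets, 83.9% female, 18-24 modal, 96% single-tweet users).
source("analysis/00_common.R")

cfg <- study_cfg()
lexicon <- read_lexicon_json(file.path(RESULTS_DIR, "lexicon.json"))

survey <- generate_survey(cfg)
cat("Survey cohort:", nrow(survey), "respondents;",
    sprintf("%.1f%% female\n", 100 * mean(survey$sex == "female")))
cat(sprintf("  fatigue affected overall: %.3f\n",
            mean(survey$item_fatigue >= 1)))
write_survey_csv(survey, file.path(RESULTS_DIR, "survey.csv"))

tweets <- generate_tweets(cfg, lexicon)
per_user <- table(tweets$user_id)
cat("Tweet stream:", nrow(tweets), "tweets from", length(per_user),
    "users;", sprintf("%.1f%% single-tweet users\n",
                      100 * mean(per_user == 1)))
cat(sprintf("  %.1f%% female, %.1f%% retweets\n",
            100 * mean(tweets$sex == "female"),
            100 * mean(tweets$is_retweet)))
write_tweets_jsonl(tweets, file.path(RESULTS_DIR, "tweets.jsonl"))
cat("-> survey.csv, tweets.jsonl\n")
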