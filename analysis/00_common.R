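# Shared settings for the numbered analysis scripts. Each script is a thin
# driver over the phqtrends package: run them in order from the repository
# root, e.g.  Rscript analysis/01_build_lexicon.R
suppressMessages(library(phqtrends))

RESULTS_DIR <- "results/analysis"
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

# one seed drives the whole workflow; 2020-03-22 was the first day of the
# German contact ban
RUN_SEED <- 20200322L

study_cfg <- function() synth_config(n_respondents = 9011L,
                                     n_users = 80000L,
                                     rng_seed = RUN_SEED)
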