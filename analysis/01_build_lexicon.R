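# Build the PHQ-8-anchored symptom lexicon: seed keywords per symptom,
# a synthetic German enrichment corpus, a PPMI+SVD embedding trained on
# it, and the expanded lexicon at the default threshold.
source("analysis/00_common.R")

seeds <- build_seed_sets(default_seed_table())
cat("Seed sets:", nrow(seeds), "keywords across",
    length(unique(seeds$symptom)), "symptoms\n")

corpus <- generate_corpus(study_cfg(), default_seed_table(),
                          default_related_words())
cat("Enrichment corpus:", length(corpus), "documents\n")
writeLines(corpus, file.path(RESULTS_DIR, "enrichment_corpus.txt"))

phrases <- grep(" ", unlist(c(default_seed_table(),
                              default_related_words())), value = TRUE)
space <- train_embedding(corpus, window = 4L, dim = 30L, min_count = 2L,
                         phrases = phrases)
cat("Embedding:", length(space$vocabulary), "tokens x",
    ncol(space$vectors), "dims\n")

lexicon <- expand_lexicon(seeds, space, tau = 0.4, k = 25L)
n_exp <- sum(lexicon$provenance == "expanded")
cat("Expanded lexicon:", nrow(lexicon), "keywords (", n_exp, "expanded )\n")
cat("Every planted related word recovered:",
    all(unlist(default_related_words()) %in% lexicon$keyword), "\n")

write_lexicon_json(lexicon, file.path(RESULTS_DIR, "lexicon.json"))
cat("-> ", RESULTS_DIR, "/lexicon.json\n", sep = "")
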