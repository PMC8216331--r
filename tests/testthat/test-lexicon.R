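test_that("seed sets normalize, deduplicate and validate", {
  s <- build_seed_sets(list(depressed_mood = c("a", "A", " a ")))
  expect_equal(nrow(s), 1L)
  expect_equal(s$keyword, "a")
  s1 <- build_seed_sets(list(fatigue_energy_loss = "X"))
  expect_equal(s1$keyword, "x")
  expect_error(build_seed_sets(list(depressed_mood = character())),
               "depressed_mood")
  expect_error(build_seed_sets(list(not_a_symptom = "x")), "unknown symptom")
  # the shipped depressed-mood seeds are the published triple
  d <- build_seed_sets(default_seed_table())
  expect_setequal(d$keyword[d$symptom == "depressed_mood"],
                  c("niedergeschlagenheit", "schwermut",
                    "hoffnungslosigkeit"))
})

test_that("embedding training is deterministic and filters rare tokens", {
  corpus <- c(rep("links rechts", 10), "einmalwort links rechts",
              rep("oben unten", 10))
  sp <- train_embedding(corpus, window = 2L, dim = 2L, min_count = 2L)
  expect_false("einmalwort" %in% sp$vocabulary)
  sp2 <- train_embedding(corpus, window = 2L, dim = 2L, min_count = 2L)
  expect_identical(sp$vectors, sp2$vectors)
  expect_error(train_embedding(corpus, dim = 100L), "smaller dim")
  expect_error(train_embedding(character()), "empty corpus")
})

test_that("tokens with identical context distributions are cosine-1 neighbours", {
  # distributional similarity is second-order: what makes two tokens
  # synonyms to the model is sharing contexts, not co-occurring directly
  corpus <- c(rep("anis zimt", 10), rep("anis zucker", 10),
              rep("salz pfeffer", 10))
  sp <- train_embedding(corpus, window = 2L, dim = 4L, min_count = 2L)
  nb <- embedding_neighbours(sp, "zimt")
  expect_equal(nb$token[1L], "zucker")
  expect_equal(unname(nb$similarity[1L]), 1, tolerance = 1e-10)
  expect_lt(nb$similarity[nb$token == "pfeffer"], 1)
})

test_that("expansion keeps the top-k highest-cosine candidates, ties lexicographic", {
  # hand-built space: 10 candidates at controlled cosines to the seed
  set.seed(1)
  seed_vec <- c(1, 0)
  angles <- c(0.10, 0.15, 0.15, 0.30, 0.45, 0.60, 0.75, 0.90, 1.05, 1.20)
  cand <- t(vapply(angles, function(a) c(cos(a), sin(a)), numeric(2L)))
  vocab <- c("seedword", paste0("kand", letters[1:10]))
  vecs <- rbind(seed_vec, cand)
  rownames(vecs) <- vocab
  space <- structure(list(vocabulary = vocab, vectors = vecs),
                     class = "embedding_space")
  seeds <- build_seed_sets(list(depressed_mood = "seedword"))
  lex <- expand_lexicon(seeds, space, tau = 0, k = 3L)
  got <- lex$keyword[lex$provenance == "expanded"]
  expect_equal(got, brute_expand_one(space, "seedword", 0, 3L, "seedword"))
  # kandb/kandc tie at the same angle: lexicographic order decides
  expect_equal(sort(got), c("kanda", "kandb", "kandc"))
})

test_that("expansion agrees with a brute-force cosine scan over the vocabulary", {
  cfg <- synth_config(rng_seed = 77L)
  corpus <- generate_corpus(cfg, default_seed_table(),
                            default_related_words())
  phrases <- grep(" ", unlist(c(default_seed_table(),
                                default_related_words())), value = TRUE)
  space <- train_embedding(corpus, window = 4L, dim = 20L, min_count = 2L,
                           phrases = phrases)
  expect_lte(length(space$vocabulary), 500L)
  seeds <- build_seed_sets(default_seed_table())
  for (tau in c(0.3, 0.6)) {
    lex <- expand_lexicon(seeds, space, tau = tau, k = 25L)
    for (sym in phq_symptoms) {
      sym_seeds <- seeds$keyword[seeds$symptom == sym]
      expected <- unique(unlist(lapply(
        gsub(" ", "_", sym_seeds), function(tok) {
          if (!tok %in% space$vocabulary) return(character())
          gsub("_", " ",
               brute_expand_one(space, tok, tau, 25L,
                                gsub(" ", "_", sym_seeds)))
        })))
      got <- lex$keyword[lex$symptom == sym & lex$provenance == "expanded"]
      expect_setequal(got, setdiff(expected, sym_seeds))
    }
  }
})

test_that("lowering tau never removes keywords; seeds-only matches are a subset", {
  cfg <- synth_config(rng_seed = 13L)
  corpus <- generate_corpus(cfg, default_seed_table(),
                            default_related_words())
  space <- train_embedding(corpus, window = 4L, dim = 20L, min_count = 2L)
  seeds <- build_seed_sets(default_seed_table())
  taus <- c(0.9, 0.7, 0.5, 0.3, 0.1)
  lexes <- lapply(taus, function(tau)
    expand_lexicon(seeds, space, tau = tau, k = 1000L))
  for (i in seq_len(length(taus) - 1L)) {
    hi <- paste(lexes[[i]]$symptom, lexes[[i]]$keyword)
    lo <- paste(lexes[[i + 1L]]$symptom, lexes[[i + 1L]]$keyword)
    expect_true(all(hi %in% lo))
  }
  # tau = 1 with no perfect duplicates: lexicon is exactly the seeds
  lex1 <- expand_lexicon(seeds, space, tau = 1, k = 10L)
  ex <- lex1[lex1$provenance == "expanded", ]
  expect_true(all(ex$score >= 1 - 1e-12))
  # match sets with the seeds-only lexicon are subsets of the expanded ones
  texts <- c("ich bin so bedrückt heute",
             "schwermut ohne ende", "alles ist aussichtslos")
  big <- lexes[[5L]]
  for (tx in texts) {
    expect_true(all(match_keywords(tx, seeds_as_lexicon(seeds)) %in%
                      match_keywords(tx, big)))
  }
})

test_that("the synthetic corpus supports recovering planted related words", {
  cfg <- synth_config(rng_seed = 55L)
  corpus <- generate_corpus(cfg, list(depressed_mood = "schwermut"),
                            list(depressed_mood = "bedrückt"))
  space <- train_embedding(corpus, window = 4L, dim = 5L, min_count = 2L)
  seeds <- build_seed_sets(list(depressed_mood = "schwermut"))
  lex <- expand_lexicon(seeds, space, tau = 0.4, k = 25L)
  expect_true("bedrückt" %in% lex$keyword[lex$provenance == "expanded"])

  # without distractors a single related word is the top-1 neighbour
  corpus0 <- generate_corpus(cfg, list(depressed_mood = "schwermut"),
                             list(depressed_mood = "bedrückt"),
                             distractor_words = character())
  sp0 <- train_embedding(corpus0, window = 4L, dim = 3L, min_count = 2L)
  expect_equal(embedding_neighbours(sp0, "schwermut")$token[1L], "bedrückt")
})

test_that("keyword matching is exact, hashtag-aware and token-level", {
  lex <- tiny_lexicon()
  expect_equal(
    match_keywords("Ja schon...Ich fühle mich immer so energielos.", lex),
    "fatigue_energy_loss")
  expect_equal(match_keywords("#Hoffnungslosigkeit überall",
                              default_lexicon()),
               "depressed_mood")
  expect_equal(match_keywords("Energie", lex), character(0))   # no substring
  expect_equal(match_keywords("", lex), character(0))
  # multi-word keyword needs a contiguous run
  expect_equal(match_keywords("keine lust auf gar nichts", lex),
               "diminished_interest")
  expect_equal(match_keywords("keine große lust", lex), character(0))
  # one text can report several symptoms
  both <- match_keywords("so energielos und alles wertlos", lex)
  expect_setequal(both, c("fatigue_energy_loss", "worthlessness_guilt"))
})

test_that("lexicon JSON serialization round-trips", {
  lex <- default_lexicon()
  path <- withr::local_tempfile(fileext = ".json")
  write_lexicon_json(lex, path)
  back <- read_lexicon_json(path)
  expect_equal(as.data.frame(back), as.data.frame(lex))
})

test_that("seeds absent from the embedding space expand to nothing, with a note", {
  corpus <- c(rep("zimt zucker", 10))
  sp <- train_embedding(corpus, window = 2L, dim = 2L, min_count = 2L)
  seeds <- build_seed_sets(list(depressed_mood = "schwermut"))
  expect_message(lex <- expand_lexicon(seeds, sp, tau = 0.4, k = 5L),
                 "absent from embedding vocabulary")
  expect_equal(lex$provenance, "seed")
})
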