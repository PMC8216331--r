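#' Default German seed keywords per PHQ-8 symptom
#'
#' Manually curated seed keywords anchoring each retained PHQ-8 symptom to
#' its questionnaire item, in German. The depressed-mood seeds are the
#' published triple "Niedergeschlagenheit" (dejection), "Schwermut"
#' (melancholy) and "Hoffnungslosigkeit" (hopelessness); seeds for the
#' other four symptoms are this package's own curation anchored to the
#' item wording and to example posts. Multi-word seeds ("keine lust") are
#' matched as contiguous token runs.
#'
#' @return Named list: symptom -> character vector of seed words.
#' @export
default_seed_table <- function() {
  list(
    diminished_interest = c("keine lust", "interesselosigkeit", "freudlosigkeit"),
    depressed_mood = c("niedergeschlagenheit", "schwermut", "hoffnungslosigkeit"),
    insomnia_hypersomnia = c("schlaflosigkeit", "einschlafprobleme", "durchschlafprobleme"),
    fatigue_energy_loss = c("energielos", "erschöpfung", "antriebslosigkeit"),
    worthlessness_guilt = c("wertlos", "versager", "schuldgefühle")
  )
}

#' Default expansion candidates per symptom
#'
#' Semantically related words and phrases that the enrichment corpus embeds
#' near the corresponding seeds, so that embedding-based expansion can
#' recover them. For depressed mood these are the published enrichment
#' examples ("aussichtslos", "ausweglos", "bedrückt", "entmutigt",
#' "schlechte stimmung"); the remainder are the package's own curation.
#' Used as ground truth by the synthetic enrichment-corpus generator.
#'
#' @return Named list: symptom -> character vector of related words.
#' @export
default_related_words <- function() {
  list(
    diminished_interest = c("lustlos", "gleichgültig", "desinteresse"),
    depressed_mood = c("aussichtslos", "ausweglos", "bedrückt", "entmutigt",
                       "schlechte stimmung"),
    insomnia_hypersomnia = c("insomnie", "schlafstörung", "wachgelegen"),
    fatigue_energy_loss = c("energielosigkeit", "ausgelaugt", "kraftlos",
                            "erschöpft"),
    worthlessness_guilt = c("enttäuschung", "nicht ertragen", "selbstzweifel",
                            "nutzlos")
  )
}

#' Build normalized seed keyword sets
#'
#' Lowercases and trims each keyword, deduplicates after normalization, and
#' returns one seed set per retained symptom.
#'
#' @param item_definitions Named list, symptom -> non-empty character
#'   vector of keywords. Names must be drawn from [phq_symptoms].
#' @return A tibble with columns `symptom`, `keyword` (class
#'   `seed_sets`).
#' @examples
#' build_seed_sets(list(depressed_mood = c("Schwermut", "schwermut ")))
#' @export
build_seed_sets <- function(item_definitions = default_seed_table()) {
  if (!is.list(item_definitions) || is.null(names(item_definitions)))
    abort_config("item_definitions", "need a named list of keyword vectors")
  bad <- setdiff(names(item_definitions), phq_symptoms)
  if (length(bad))
    abort_config("item_definitions", paste("unknown symptom:", bad[1L]))
  rows <- lapply(names(item_definitions), function(sym) {
    words <- item_definitions[[sym]]
    words <- trimws(tolower(as.character(words)))
    words <- unique(words[nzchar(words)])
    if (length(words) == 0L)
      abort_config("item_definitions", paste("no seed words for", sym))
    tibble::tibble(symptom = sym, keyword = words)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("seed_sets", class(out))
  out
}

new_symptom_lexicon <- function(df) {
  df <- dplyr::arrange(df, .data$symptom, .data$provenance, .data$keyword)
  class(df) <- unique(c("symptom_lexicon", class(df)))
  df
}

#' Turn seed sets into a (seeds-only) symptom lexicon
#'
#' @param seeds A `seed_sets` tibble from [build_seed_sets()].
#' @return A `symptom_lexicon` tibble with columns `symptom`, `keyword`,
#'   `provenance` (`"seed"`) and `score` (`NA` for seeds).
#' @export
seeds_as_lexicon <- function(seeds) {
  new_symptom_lexicon(tibble::tibble(
    symptom = seeds$symptom, keyword = seeds$keyword,
    provenance = "seed", score = NA_real_
  ))
}

#' Expand seed sets into a symptom lexicon via embedding neighbours
#'
#' For every seed word present in the embedding space, the `k` nearest
#' vocabulary neighbours with cosine similarity at least `tau` are added as
#' `expanded` keywords of the seed's symptom (ties in similarity broken
#' lexicographically). Neighbours already among the symptom's seeds are not
#' duplicated; when several seeds of one symptom propose the same word its
#' highest similarity is kept. Seeds absent from the space contribute no
#' expansions (reported via `message()`). Multi-word phrases travel as
#' underscore-joined embedding tokens and are returned as space-separated
#' keywords.
#'
#' @param seeds A `seed_sets` tibble.
#' @param space An `embedding_space` from [train_embedding()].
#' @param tau Cosine similarity threshold in \[0, 1\]. Default 0.4.
#' @param k Maximum neighbours kept per seed word. Default 25.
#' @param deny Optional character vector of keywords never admitted
#'   (manual-curation hook).
#' @param allow Optional named list, symptom -> keywords force-added with
#'   provenance `"curated"`.
#' @return A `symptom_lexicon` tibble.
#' @export
expand_lexicon <- function(seeds, space, tau = 0.4, k = 25L,
                           deny = character(), allow = list()) {
  stopifnot(inherits(space, "embedding_space"))
  if (tau < 0 || tau > 1) abort_config("tau", "must be in [0, 1]")
  if (k < 0) abort_config("k", "must be >= 0")
  deny <- tolower(deny)

  lex <- seeds_as_lexicon(seeds)
  rows <- list(lex)
  for (sym in unique(seeds$symptom)) {
    sym_seeds <- seeds$keyword[seeds$symptom == sym]
    sym_tokens <- gsub(" ", "_", sym_seeds, fixed = TRUE)
    for (i in seq_along(sym_seeds)) {
      tok <- sym_tokens[i]
      if (!tok %in% space$vocabulary) {
        message("seed '", sym_seeds[i], "' (", sym,
                ") absent from embedding vocabulary; no expansions")
        next
      }
      sims <- embedding_neighbours(space, tok)
      cand <- sims[sims$similarity >= tau, , drop = FALSE]
      cand$keyword <- gsub("_", " ", cand$token, fixed = TRUE)
      cand <- cand[!cand$keyword %in% c(sym_seeds, deny), , drop = FALSE]
      cand <- cand[order(-cand$similarity, cand$keyword), , drop = FALSE]
      cand <- head(cand, k)
      if (nrow(cand))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          symptom = sym, keyword = cand$keyword,
          provenance = "expanded", score = cand$similarity
        )
    }
  }
  for (sym in names(allow)) {
    extra <- setdiff(tolower(allow[[sym]]), deny)
    if (length(extra))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        symptom = sym, keyword = extra,
        provenance = "curated", score = NA_real_
      )
  }
  out <- dplyr::bind_rows(rows)
  # seeds win over expanded duplicates; otherwise keep the best score
  out <- dplyr::slice_head(
    dplyr::arrange(
      dplyr::group_by(out, .data$symptom, .data$keyword),
      factor(.data$provenance, levels = c("seed", "expanded", "curated")),
      dplyr::desc(.data$score)
    ),
    n = 1L
  )
  new_symptom_lexicon(dplyr::ungroup(out))
}

#' Match a text against a symptom lexicon
#'
#' Exact token-sequence matching: a symptom is reported iff at least one of
#' its lexicon keywords occurs in the text as a contiguous run of tokens
#' after normalization (lowercasing, hashtag `#` stripping). No substring,
#' stem or fuzzy matching: "Energie" does not match the keyword
#' "energielos".
#'
#' @param text A single string.
#' @param lexicon A `symptom_lexicon` tibble.
#' @return Character vector of matched symptom identifiers (possibly
#'   empty), in [phq_symptoms] order.
#' @examples
#' lex <- seeds_as_lexicon(build_seed_sets())
#' match_keywords("Ja schon...Ich fühle mich immer so energielos.", lex)
#' @export
match_keywords <- function(text, lexicon) {
  match_symptoms_batch(text, lexicon)[[1L]]
}

# vectorized matcher: one tokenization pass, single-token keywords via set
# membership, multi-token keywords via contiguous-run scan restricted to
# documents containing the first token
match_symptoms_batch <- function(texts, lexicon) {
  docs <- tokenize_text(texts)
  by_sym <- split(lexicon$keyword, lexicon$symptom)
  hit <- matrix(FALSE, length(docs), length(by_sym),
                dimnames = list(NULL, names(by_sym)))
  for (sym in names(by_sym)) {
    kws <- strsplit(by_sym[[sym]], " ", fixed = TRUE)
    singles <- unlist(kws[lengths(kws) == 1L], use.names = FALSE)
    multis <- kws[lengths(kws) > 1L]
    h <- vapply(docs, function(tok) any(tok %in% singles), logical(1L))
    for (kw in multis) {
      cand <- which(!h & vapply(docs, function(tok) kw[1L] %in% tok,
                                logical(1L)))
      h[cand] <- vapply(docs[cand], contains_run, logical(1L), needle = kw)
    }
    hit[, sym] <- h
  }
  order_cols <- intersect(phq_symptoms, colnames(hit))
  lapply(seq_len(nrow(hit)), function(i)
    order_cols[hit[i, order_cols]])
}

#' The package's shipped default lexicon
#'
#' Builds the default seed sets and expands them over a deterministic
#' synthetic enrichment corpus (built by [generate_corpus()] from the
#' shipped seed and related-word tables with a fixed internal seed), so
#' every expanded entry carries a genuine cosine score. The result is
#' cached for the session.
#'
#' @param tau,k Expansion threshold and neighbour budget, see
#'   [expand_lexicon()].
#' @return A `symptom_lexicon` tibble containing the seeds plus the
#'   recovered related words.
#' @export
default_lexicon <- function(tau = 0.4, k = 25L) {
  key <- sprintf("tau=%g k=%d", tau, k)
  cached <- lexicon_cache[[key]]
  if (!is.null(cached)) return(cached)
  seeds <- build_seed_sets(default_seed_table())
  related <- default_related_words()
  corpus <- generate_corpus(
    synth_config(rng_seed = 20200101L), seed_words = default_seed_table(),
    related_words = related
  )
  phrases <- grep(" ", unlist(c(default_seed_table(), related),
                              use.names = FALSE), value = TRUE)
  space <- train_embedding(corpus, window = 4L, dim = 30L, min_count = 2L,
                           phrases = phrases)
  lex <- expand_lexicon(seeds, space, tau = tau, k = k)
  lexicon_cache[[key]] <- lex
  lex
}

lexicon_cache <- new.env(parent = emptyenv())

#' Serialize / read a symptom lexicon as JSON
#'
#' Format: object mapping symptom -> array of `{keyword, provenance,
#' score}` entries (score `null` for seeds).
#'
#' @param lexicon A `symptom_lexicon`.
#' @param path File path.
#' @return `write_lexicon_json()` returns `path` invisibly;
#'   `read_lexicon_json()` a `symptom_lexicon`.
#' @export
write_lexicon_json <- function(lexicon, path) {
  by_sym <- split(lexicon[c("keyword", "provenance", "score")],
                  lexicon$symptom)
  jsonlite::write_json(by_sym, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_lexicon_json
#' @export
read_lexicon_json <- function(path) {
  by_sym <- jsonlite::read_json(path, simplifyVector = TRUE)
  rows <- lapply(names(by_sym), function(sym) {
    df <- by_sym[[sym]]
    tibble::tibble(symptom = sym, keyword = df$keyword,
                   provenance = df$provenance,
                   score = as.numeric(df$score %||% NA_real_))
  })
  new_symptom_lexicon(dplyr::bind_rows(rows))
}
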