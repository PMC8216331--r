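#' Train a deterministic word-embedding space
#'
#' A transparent, fully deterministic embedding backend: token
#' co-occurrence counts within a symmetric window are reweighted by
#' positive pointwise mutual information (PPMI) and factorized by truncated
#' SVD; a token's vector is the corresponding row of \eqn{U_d \Sigma_d^{1/2}}.
#' The sign of each singular vector is fixed by making its
#' largest-magnitude component positive, so repeated training on the same
#' corpus is byte-identical. Any deterministic backend producing an
#' `embedding_space` (a vocabulary plus one fixed-length vector per token)
#' can be swapped in behind the same contract.
#'
#' @param corpus Character vector: one document per element, UTF-8 plain
#'   text.
#' @param window Symmetric co-occurrence window in tokens. Default 4.
#' @param dim Embedding dimensionality; must not exceed the retained
#'   vocabulary size. Default 50.
#' @param min_count Tokens occurring fewer times are dropped. Default 2.
#' @param phrases Multi-word expressions (space-separated, lowercase) to
#'   merge into single underscore-joined tokens before counting.
#' @return An object of class `embedding_space`: list with `vocabulary`
#'   (character) and `vectors` (numeric matrix, one row per token).
#' @export
train_embedding <- function(corpus, window = 4L, dim = 50L, min_count = 2L,
                            phrases = character()) {
  corpus <- as.character(corpus)
  corpus <- corpus[nzchar(trimws(corpus))]
  if (length(corpus) == 0L) stop("empty corpus", call. = FALSE)
  docs <- tokenize_text(corpus)
  if (length(phrases)) docs <- lapply(docs, merge_phrases, phrases = tolower(phrases))

  counts <- table(unlist(docs, use.names = FALSE))
  vocab <- sort(names(counts)[counts >= min_count])
  v <- length(vocab)
  if (v < dim)
    stop(sprintf(
      "vocabulary after min-count filtering has %d tokens, fewer than dim = %d; choose a smaller dim",
      v, dim), call. = FALSE)

  C <- matrix(0, v, v, dimnames = list(vocab, vocab))
  for (tok in docs) {
    ids <- match(tok, vocab)
    keep <- !is.na(ids)
    ids <- ids[keep]
    n <- length(ids)
    if (n < 2L) next
    for (off in seq_len(min(window, n - 1L))) {
      a <- ids[seq_len(n - off)]
      b <- ids[seq_len(n - off) + off]
      for (j in seq_along(a)) {
        C[a[j], b[j]] <- C[a[j], b[j]] + 1
        C[b[j], a[j]] <- C[b[j], a[j]] + 1
      }
    }
  }

  total <- sum(C)
  if (total == 0) stop("no co-occurrences found; corpus too sparse", call. = FALSE)
  rs <- rowSums(C)
  # PPMI: max(0, log(p(a,b) / (p(a) p(b))))
  P <- log(pmax(C, 0) * total / outer(rs, rs))
  P[!is.finite(P) | P < 0] <- 0

  dec <- svd(P, nu = dim, nv = 0L)
  U <- dec$u
  d <- dec$d[seq_len(dim)]
  for (j in seq_len(dim)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  vectors <- U * rep(sqrt(pmax(d, 0)), each = v)
  rownames(vectors) <- vocab
  structure(list(vocabulary = vocab, vectors = vectors),
            class = "embedding_space")
}

#' @export
print.embedding_space <- function(x, ...) {
  cat(sprintf("<embedding_space: %d tokens x %d dimensions>\n",
              length(x$vocabulary), ncol(x$vectors)))
  invisible(x)
}

#' Cosine similarity of a token to the whole vocabulary
#'
#' @param space An `embedding_space`.
#' @param token A vocabulary token (multi-word phrases underscore-joined).
#' @return Tibble with columns `token`, `similarity`, sorted by decreasing
#'   similarity (the query token itself excluded). Zero-vector tokens get
#'   similarity 0.
#' @export
embedding_neighbours <- function(space, token) {
  stopifnot(inherits(space, "embedding_space"))
  i <- match(token, space$vocabulary)
  if (is.na(i)) stop("token not in vocabulary: ", token, call. = FALSE)
  q <- space$vectors[i, ]
  sims <- cosine_to_all(space$vectors, q)
  out <- tibble::tibble(token = space$vocabulary, similarity = sims)
  out <- out[-i, , drop = FALSE]
  out[order(-out$similarity, out$token), , drop = FALSE]
}

cosine_to_all <- function(M, q) {
  qn <- sqrt(sum(q^2))
  rn <- sqrt(rowSums(M^2))
  denom <- rn * qn
  s <- as.numeric(M %*% q)
  ifelse(denom > 0, s / denom, 0)
}
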