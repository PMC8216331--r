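#' Tokenize text for keyword matching and embedding training
#'
#' Unicode-aware word tokenizer: lowercases, splits on any run of
#' characters that is neither a letter nor a digit, and strips a leading
#' `#` from hashtag tokens so hashtagged keyword mentions match their
#' plain-text form. No stemming or lemmatization is applied — downstream
#' keyword detection is an exact-match contract that stemming would
#' violate.
#'
#' @param text Character vector of documents.
#' @return A list of character vectors, one per input document (empty
#'   character vector for empty or punctuation-only input).
#' @examples
#' tokenize_text("#Hoffnungslosigkeit überall")
#' @export
tokenize_text <- function(text) {
  text <- tolower(as.character(text))
  # keep '#' through the split, then strip it from token starts
  parts <- strsplit(text, "[^\\p{L}\\p{N}#]+", perl = TRUE)
  lapply(parts, function(tok) {
    tok <- sub("^#+", "", tok)
    tok[nzchar(tok)]
  })
}

# Join occurrences of known multi-word phrases into single underscore
# tokens, longest phrase first. `phrases` is a character vector of
# space-separated phrases already lowercased.
merge_phrases <- function(tokens, phrases) {
  if (length(phrases) == 0L || length(tokens) == 0L) return(tokens)
  phr <- strsplit(phrases, " ", fixed = TRUE)
  phr <- phr[order(-lengths(phr))]
  for (p in phr) {
    np <- length(p)
    if (np < 2L || length(tokens) < np) next
    i <- 1L
    out <- character(0)
    while (i <= length(tokens)) {
      if (i + np - 1L <= length(tokens) &&
          all(tokens[i:(i + np - 1L)] == p)) {
        out <- c(out, paste(p, collapse = "_"))
        i <- i + np
      } else {
        out <- c(out, tokens[i])
        i <- i + 1L
      }
    }
    tokens <- out
  }
  tokens
}

# TRUE iff `needle` (character vector of tokens) occurs as a contiguous
# run inside `haystack`.
contains_run <- function(haystack, needle) {
  n <- length(needle)
  m <- length(haystack)
  if (n == 0L || m < n) return(FALSE)
  if (n == 1L) return(needle %in% haystack)
  hits <- which(haystack == needle[1L])
  hits <- hits[hits + n - 1L <= m]
  for (i in hits) {
    if (all(haystack[i:(i + n - 1L)] == needle)) return(TRUE)
  }
  FALSE
}
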