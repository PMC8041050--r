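#' Normalize free text into a token set
#'
#' Lower-cases the input, splits on non-alphanumeric characters, drops
#' stop words and de-duplicates. This is the normalization used for
#' concept matching (no stemming); the question-matching pipeline applies
#' [stem_tokens()] on top of it.
#'
#' @param text A character string (may be empty).
#' @param stopwords Character vector of stop words to drop (already
#'   lower-case). Defaults to the shipped English list, see
#'   [default_stopwords()].
#' @return A character vector of unique tokens (a set; order is first
#'   appearance). Empty input yields an empty vector.
#' @examples
#' normalize_tokens("The patient has fever", stopwords = c("the", "has"))
#' @export
normalize_tokens <- function(text, stopwords = default_stopwords()) {
  if (length(text) == 0 || is.na(text) || !nzchar(text)) return(character(0))
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks <- toks[nzchar(toks)]
  toks <- toks[!toks %in% stopwords]
  unique(toks)
}

#' Shipped English stop-word list
#'
#' Read from `inst/extdata/stopwords_en.txt` (one word per line, UTF-8);
#' users may supply their own list to any matching function.
#'
#' @return Character vector of lower-case stop words.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "vptutor")
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

#' Jaccard similarity between two token sets
#'
#' `|A n B| / |A u B|`, with the convention that two empty sets have
#' similarity 0.
#'
#' @param a,b Character vectors treated as sets (duplicates ignored).
#' @return A number in `[0, 1]`.
#' @examples
#' jaccard(c("chest", "pain", "acute"), c("chest", "pain"))
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Light suffix-stripping stemmer for the question pipeline
#'
#' A small deterministic English stemmer (plural -s/-es, -ing, -ed) used to
#' conflate inflected forms in question matching. Concept matching does not
#' stem.
#'
#' @param tokens Character vector of lower-case tokens.
#' @return Character vector of stemmed tokens, same length.
#' @export
stem_tokens <- function(tokens) {
  out <- tokens
  out <- sub("(...)ing$", "\\1", out)
  out <- sub("(...)ed$", "\\1", out)
  out <- sub("(..)ies$", "\\1y", out)
  out <- sub("(...)es$", "\\1e", out)
  long <- nchar(out) > 3
  out[long] <- sub("([^s])s$", "\\1", out[long])
  out
}

# Tokenization used throughout the question-matching pipeline: lower-case,
# split, stem; stop words are KEPT (frame words carry signal for sentence
# similarity), duplicates kept (sequences, not sets).
question_tokens <- function(text) {
  if (length(text) == 0 || is.na(text) || !nzchar(text)) return(character(0))
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks <- toks[nzchar(toks)]
  stem_tokens(toks)
}
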