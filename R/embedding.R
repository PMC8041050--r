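#' Train word embeddings with synonym supervision
#'
#' A seeded skip-gram trainer with negative sampling, augmented by a weak
#' dictionary-supervision term that pulls declared synonym pairs together
#' in the embedding space (in the spirit of dictionary-augmented
#' embeddings). Written for small in-memory corpora; intended to feed the
#' Siamese question matcher, and replaceable by any pretrained embedding
#' via [embedding_model()].
#'
#' @param corpus Character vector of sentences (non-empty).
#' @param synonym_pairs A two-column data frame (or matrix) of word pairs
#'   to attract; pairs mentioning out-of-corpus words are skipped with a
#'   warning. `NULL` for none.
#' @param dimension Embedding dimension `d >= 2` (default 16).
#' @param seed Integer seed; training is deterministic given the seed.
#' @param epochs Passes over the corpus (default 8).
#' @param window Skip-gram context half-width (default 2).
#' @param negative Negative samples per positive pair (default 3).
#' @param learning_rate SGD step size (default 0.05).
#' @param min_count Minimum corpus frequency for a word to enter the
#'   vocabulary (default 1).
#' @param synonym_weight Step size of the synonym attraction term
#'   (default 0.1), applied once per synonym pair per epoch.
#' @return An object of class `embedding_model`: `vocabulary` (named
#'   integer index), `vectors` (|V| x d matrix, rownames = words),
#'   `dimension`.
#' @export
train_embeddings <- function(corpus, synonym_pairs = NULL, dimension = 16,
                             seed = 1L, epochs = 8, window = 2, negative = 3,
                             learning_rate = 0.05, min_count = 1,
                             synonym_weight = 0.1) {
  if (length(corpus) == 0 || all(!nzchar(corpus))) {
    stop("train_embeddings: the corpus is empty")
  }
  stopifnot(dimension >= 2)
  sent_tokens <- lapply(corpus, question_tokens)
  sent_tokens <- sent_tokens[lengths(sent_tokens) > 0]
  freq <- table(unlist(sent_tokens))
  vocab_words <- sort(names(freq[freq >= min_count]))
  if (length(vocab_words) < 2) stop("train_embeddings: vocabulary too small")
  vocab <- stats::setNames(seq_along(vocab_words), vocab_words)

  syn <- NULL
  if (!is.null(synonym_pairs) && NROW(synonym_pairs) > 0) {
    syn <- as.data.frame(synonym_pairs)[, 1:2]
    names(syn) <- c("a", "b")
    syn$a <- stem_tokens(tolower(syn$a))
    syn$b <- stem_tokens(tolower(syn$b))
    known <- syn$a %in% vocab_words & syn$b %in% vocab_words
    if (any(!known)) {
      warning(sprintf("train_embeddings: skipping %d synonym pair(s) with out-of-corpus words",
                      sum(!known)))
      syn <- syn[known, , drop = FALSE]
    }
    if (nrow(syn) == 0) syn <- NULL
  }

  withr::local_seed(seed)
  V <- length(vocab)
  W_in <- matrix(stats::runif(V * dimension, -0.5, 0.5) / dimension, V, dimension,
                 dimnames = list(vocab_words, NULL))
  W_out <- matrix(0, V, dimension, dimnames = list(vocab_words, NULL))

  # unigram^(3/4) negative-sampling table
  p_neg <- as.numeric(freq[vocab_words])^0.75
  p_neg <- p_neg / sum(p_neg)

  idx_seqs <- lapply(sent_tokens, function(t) unname(vocab[t]))
  sigmoid <- function(x) 1 / (1 + exp(-x))

  for (ep in seq_len(epochs)) {
    for (s in sample(length(idx_seqs))) {
      ids <- idx_seqs[[s]]
      n <- length(ids)
      for (pos in seq_len(n)) {
        lo <- max(1, pos - window); hi <- min(n, pos + window)
        ctx <- ids[setdiff(lo:hi, pos)]
        centre <- ids[pos]
        v <- W_in[centre, ]
        for (c_id in ctx) {
          neg <- sample.int(V, negative, replace = TRUE, prob = p_neg)
          outs <- c(c_id, neg)
          lab <- c(1, numeric(negative))
          U <- W_out[outs, , drop = FALSE]
          g <- sigmoid(drop(U %*% v)) - lab           # length negative+1
          W_out[outs, ] <- U - learning_rate * (g %o% v)
          v <- v - learning_rate * drop(crossprod(U, g))
        }
        W_in[centre, ] <- v
      }
    }
    if (!is.null(syn)) {
      # dictionary supervision: shrink the gap between synonym vectors
      for (k in seq_len(nrow(syn))) {
        ia <- syn$a[k]; ib <- syn$b[k]
        gap <- W_in[ia, ] - W_in[ib, ]
        W_in[ia, ] <- W_in[ia, ] - synonym_weight * gap
        W_in[ib, ] <- W_in[ib, ] + synonym_weight * gap
      }
    }
  }

  # unit-normalize rows: downstream similarity models care about direction,
  # and a common input scale keeps the recurrent encoder's gates responsive
  W_in <- W_in / sqrt(rowSums(W_in^2))
  embedding_model(W_in)
}

#' Wrap a vector matrix as an embedding model
#'
#' @param vectors Numeric matrix, one row per word, rownames = words.
#' @return An `embedding_model`.
#' @export
embedding_model <- function(vectors) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)),
            all(is.finite(vectors)))
  structure(
    list(vocabulary = stats::setNames(seq_len(nrow(vectors)), rownames(vectors)),
         vectors = vectors, dimension = ncol(vectors)),
    class = "embedding_model"
  )
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("<embedding_model> %d words, dimension %d\n",
              length(x$vocabulary), x$dimension))
  invisible(x)
}

#' Cosine similarity between two embedded words
#'
#' @param model An [embedding_model()].
#' @param w1,w2 Words (stemmed/lower-cased internally like the training
#'   corpus).
#' @return Cosine similarity, or `NA` if either word is out of vocabulary.
#' @export
word_cosine <- function(model, w1, w2) {
  w1 <- stem_tokens(tolower(w1)); w2 <- stem_tokens(tolower(w2))
  if (!w1 %in% rownames(model$vectors) || !w2 %in% rownames(model$vectors)) {
    return(NA_real_)
  }
  a <- model$vectors[w1, ]; b <- model$vectors[w2, ]
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}
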