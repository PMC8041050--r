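#' Create a Siamese recurrent question matcher
#'
#' The matcher embeds each question word-by-word, runs a single-layer
#' gated recurrent (LSTM) encoder over the sequence and scores a pair of
#' questions by the Manhattan-distance similarity
#' `exp(-||h_a - h_b||_1)` of their final hidden states. The two branches
#' share one parameter set (structural weight sharing: there is only one
#' encoder), so the score is symmetric and equals 1 exactly for identical
#' inputs. Out-of-vocabulary words map to a dedicated trainable UNK
#' vector (zero-initialized).
#'
#' @param embedding An [embedding_model()] supplying the word vectors
#'   (frozen during matcher training; the UNK vector is trained).
#' @param hidden_size Encoder hidden state size `h` (default 50).
#' @param max_len Maximum question length in tokens; longer questions are
#'   truncated to their first `max_len` tokens (default 30).
#' @param seed Seed for the (small, uniform) encoder weight
#'   initialization.
#' @return An object of class `siamese_matcher`.
#' @export
siamese_matcher <- function(embedding, hidden_size = 50, max_len = 30,
                            seed = 1L) {
  stopifnot(inherits(embedding, "embedding_model"),
            hidden_size >= 1, max_len >= 1)
  d <- embedding$dimension
  withr::local_seed(seed)
  r <- 1 / sqrt(hidden_size + d)
  structure(
    list(
      embedding = embedding,
      hidden_size = as.integer(hidden_size),
      max_len = as.integer(max_len),
      W = matrix(stats::runif(4 * hidden_size * (d + hidden_size), -r, r),
                 4 * hidden_size, d + hidden_size),
      # forget-gate bias starts at 1 (standard LSTM initialization)
      b = rep(c(0, 1, 0, 0), each = hidden_size),
      unk = numeric(d),
      loss_trace = tibble::tibble(epoch = integer(0), loss = numeric(0))
    ),
    class = "siamese_matcher"
  )
}

#' @export
print.siamese_matcher <- function(x, ...) {
  cat(sprintf("<siamese_matcher> d=%d, hidden=%d, max_len=%d, %s\n",
              x$embedding$dimension, x$hidden_size, x$max_len,
              if (nrow(x$loss_trace)) {
                sprintf("trained %d epochs (final loss %.4f)",
                        max(x$loss_trace$epoch),
                        x$loss_trace$loss[nrow(x$loss_trace)])
              } else "untrained"))
  invisible(x)
}

# map a question to a d x T matrix of word vectors (T >= 1), truncating to
# max_len; OOV tokens take the UNK vector. Also returns which columns are UNK.
question_matrix <- function(matcher, question) {
  toks <- question_tokens(question)
  if (length(toks) == 0) {
    stop("encode: the question is empty; prompt the student for input")
  }
  toks <- toks[seq_len(min(length(toks), matcher$max_len))]
  E <- matcher$embedding$vectors
  known <- toks %in% rownames(E)
  X <- matrix(0, matcher$embedding$dimension, length(toks))
  if (any(known)) X[, known] <- t(E[toks[known], , drop = FALSE])
  if (any(!known)) X[, !known] <- matcher$unk
  list(X = X, unk_cols = which(!known))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# LSTM forward pass over X (d x T); returns final hidden state and, if
# keep_cache, everything backprop needs.
lstm_forward <- function(W, b, h_size, X, keep_cache = FALSE) {
  T_ <- ncol(X)
  h <- numeric(h_size); cc <- numeric(h_size)
  cache <- if (keep_cache) vector("list", T_) else NULL
  idx_i <- seq_len(h_size)
  for (t in seq_len(T_)) {
    z <- c(X[, t], h)
    a <- drop(W %*% z) + b
    i <- sigmoid(a[idx_i])
    f <- sigmoid(a[idx_i + h_size])
    o <- sigmoid(a[idx_i + 2L * h_size])
    g <- tanh(a[idx_i + 3L * h_size])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h <- o * tc
    if (keep_cache) cache[[t]] <- list(z = z, i = i, f = f, o = o, g = g,
                                       c_prev = c_prev, tc = tc)
  }
  list(h = h, cache = cache)
}

# backprop through time; dh_T is the gradient at the final hidden state.
# Returns gradients for W, b and the input matrix X.
lstm_backward <- function(W, h_size, d, cache, dh_T) {
  T_ <- length(cache)
  dW <- matrix(0, nrow(W), ncol(W)); db <- numeric(nrow(W))
  dX <- matrix(0, d, T_)
  dh <- dh_T; dc <- numeric(h_size)
  idx_i <- seq_len(h_size)
  for (t in rev(seq_len(T_))) {
    st <- cache[[t]]
    do <- dh * st$tc
    dc <- dc + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    dg <- dc * st$i
    df <- dc * st$c_prev
    dc <- dc * st$f
    da <- c(di * st$i * (1 - st$i),
            df * st$f * (1 - st$f),
            do * st$o * (1 - st$o),
            dg * (1 - st$g^2))
    dW <- dW + tcrossprod(da, st$z)
    db <- db + da
    dz <- drop(crossprod(W, da))
    dX[, t] <- dz[seq_len(d)]
    dh <- dz[(d + 1L):(d + h_size)]
  }
  list(dW = dW, db = db, dX = dX)
}

#' Encode a question into the matcher's hidden state
#'
#' Tokenizes (lower-case, light stemming), maps tokens to embedding
#' vectors (UNK for out-of-vocabulary), truncates to the matcher's
#' maximum length and returns the final hidden state of the recurrent
#' encoder. Deterministic.
#'
#' @param matcher A [siamese_matcher()].
#' @param question Non-empty question text.
#' @return Numeric vector of length `hidden_size`.
#' @export
encode <- function(matcher, question) {
  stopifnot(inherits(matcher, "siamese_matcher"))
  qm <- question_matrix(matcher, question)
  lstm_forward(matcher$W, matcher$b, matcher$hidden_size, qm$X)$h
}

#' Semantic-equivalence score of a question pair
#'
#' `exp(-||encode(q1) - encode(q2)||_1)`: the Manhattan-distance
#' similarity of the Siamese-network literature. Symmetric; in `(0, 1]`;
#' equals 1 exactly iff the hidden states coincide (in particular for
#' identical questions).
#'
#' @param matcher A [siamese_matcher()].
#' @param q1,q2 Non-empty question texts.
#' @return A score in `(0, 1]`.
#' @export
pair_similarity <- function(matcher, q1, q2) {
  h1 <- encode(matcher, q1)
  h2 <- encode(matcher, q2)
  exp(-sum(abs(h1 - h2)))
}

#' Train the Siamese matcher on labeled question pairs
#'
#' Minimizes the squared error between the pair similarity
#' `exp(-||h_a - h_b||_1)` and the binary equivalence label by
#' backpropagation through time with Adam updates (one pair per step,
#' shuffled each epoch). Both branches accumulate gradient into the single
#' shared parameter set. Word vectors stay frozen; the UNK vector trains.
#' Because small-corpus recurrent training can stall in optima that do
#' not generalize, the optimization is restarted from `restarts` seeded
#' initializations; within each restart, each epoch (and the tail average
#' of the final quarter of epochs) is scored on a held-back slice of the
#' labeled pairs by a retrieval-style criterion — each equivalent pair's
#' paraphrase must rank its own anchor question first among the slice's
#' anchors — and the best checkpoint across restarts is kept. This
#' mirrors what the downstream question ranker consumes; model selection
#' uses only the training pairs, never evaluation data. Deterministic
#' given `seed`.
#'
#' @param matcher A [siamese_matcher()].
#' @param pairs Data frame with columns `question_a`, `question_b`,
#'   `equivalent` (0/1). Both labels must be present.
#' @param epochs Number of passes (>= 1; default 80).
#' @param learning_rate Adam step size (default 0.02).
#' @param seed Seed controlling the validation split, shuffling and
#'   restart initializations.
#' @param restarts Number of seeded restarts (default 5); the first
#'   restart starts from the matcher's current weights, later ones from
#'   fresh initializations.
#' @param validation Fraction of `pairs` held back to pick the winning
#'   restart (default 0.15); with `validation = 0` or a single restart,
#'   all pairs are used for training and selection falls back to the
#'   final training loss.
#' @return The trained `siamese_matcher`, with `$loss_trace` extended by
#'   one row (epoch, mean squared loss) per epoch of the winning restart.
#' @export
train_matcher <- function(matcher, pairs, epochs = 80, learning_rate = 0.02,
                          seed = 1L, restarts = 5, validation = 0.15) {
  stopifnot(inherits(matcher, "siamese_matcher"))
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("question_a", "question_b", "equivalent") %in% names(pairs)))
  if (epochs < 1) stop("train_matcher: epochs must be >= 1")
  y <- as.numeric(pairs$equivalent)
  if (length(unique(y)) < 2) {
    stop("train_matcher: training pairs contain a single class; ",
         "both equivalent and inequivalent pairs are required")
  }

  h_size <- matcher$hidden_size
  d <- matcher$embedding$dimension
  n <- nrow(pairs)
  # tokenize once; re-resolve UNK columns per question (vocab is fixed)
  qmats <- lapply(seq_len(n), function(k) {
    list(a = question_matrix(matcher, pairs$question_a[k]),
         b = question_matrix(matcher, pairs$question_b[k]))
  })

  refresh_unk <- function(qm, unk) {
    if (length(qm$unk_cols)) qm$X[, qm$unk_cols] <- unk
    qm$X
  }

  pair_sims <- function(params, idx) {
    vapply(idx, function(k) {
      Xa <- refresh_unk(qmats[[k]]$a, params$unk)
      Xb <- refresh_unk(qmats[[k]]$b, params$unk)
      ha <- lstm_forward(params$W, params$b, h_size, Xa)$h
      hb <- lstm_forward(params$W, params$b, h_size, Xb)$h
      exp(-sum(abs(ha - hb)))
    }, numeric(1))
  }

  # checkpoint score on the validation slice. The downstream consumer is a
  # retrieval ranker, so the criterion is retrieval-style: each equivalent
  # validation pair contributes a query (its second question) that must
  # rank its own anchor (the first question) above the anchors of the
  # other validation pairs; score = error rate, squared error as
  # tie-breaker. Falls back to plain squared error when the slice has no
  # equivalent pairs.
  make_val_scorer <- function(idx) {
    yv <- y[idx]
    pos <- idx[yv == 1]
    anchors <- unique(vapply(idx, function(k) pairs$question_a[k], character(1)))
    anchor_mats <- lapply(anchors, function(txt) question_matrix(matcher, txt))
    anchor_of <- match(vapply(pos, function(k) pairs$question_a[k],
                              character(1)), anchors)
    function(params) {
      s <- pair_sims(params, idx)
      mse <- mean((s - yv)^2)
      if (length(pos) < 2 || length(anchors) < 2) return(mse)
      H <- vapply(anchor_mats, function(qm) {
        lstm_forward(params$W, params$b, h_size,
                     refresh_unk(qm, params$unk))$h
      }, numeric(h_size))
      hits <- vapply(seq_along(pos), function(j) {
        Xq <- refresh_unk(qmats[[pos[j]]]$b, params$unk)
        hq <- lstm_forward(params$W, params$b, h_size, Xq)$h
        d <- colSums(abs(H - hq))
        which.min(d) == anchor_of[j]
      }, logical(1))
      (1 - mean(hits)) + 0.001 * mse
    }
  }

  # trains on train_idx; the candidate parameters of a run are the average
  # of the final quarter of epochs (tail/Polyak averaging smooths SGD
  # iterate noise); with a validation set, the per-epoch checkpoint with
  # the best validation score competes with the tail average
  run_training <- function(params, train_idx, val_idx) {
    adam_m <- lapply(params, function(p) p * 0)
    adam_v <- lapply(params, function(p) p * 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; step <- 0L
    trace <- numeric(epochs)
    best_params <- params; best_val <- Inf
    avg_from <- max(1L, epochs - ceiling(epochs / 4) + 1L)
    avg_params <- NULL; avg_n <- 0L
    for (ep in seq_len(epochs)) {
      tot <- 0
      for (k in sample(train_idx)) {
        Xa <- refresh_unk(qmats[[k]]$a, params$unk)
        Xb <- refresh_unk(qmats[[k]]$b, params$unk)
        fa <- lstm_forward(params$W, params$b, h_size, Xa, keep_cache = TRUE)
        fb <- lstm_forward(params$W, params$b, h_size, Xb, keep_cache = TRUE)
        diff <- fa$h - fb$h
        s <- exp(-sum(abs(diff)))
        err <- s - y[k]
        tot <- tot + err^2
        # dL/dh_a = 2*err * s * (-sign(diff)); dL/dh_b is its negative
        dha <- -2 * err * s * sign(diff)
        ba <- lstm_backward(params$W, h_size, d, fa$cache, dha)
        bb <- lstm_backward(params$W, h_size, d, fb$cache, -dha)
        g <- list(W = ba$dW + bb$dW, b = ba$db + bb$db, unk = numeric(d))
        ua <- qmats[[k]]$a$unk_cols; ub <- qmats[[k]]$b$unk_cols
        if (length(ua)) g$unk <- g$unk + rowSums(ba$dX[, ua, drop = FALSE])
        if (length(ub)) g$unk <- g$unk + rowSums(bb$dX[, ub, drop = FALSE])

        step <- step + 1L
        corr <- sqrt(1 - beta2^step) / (1 - beta1^step)
        for (nm in names(params)) {
          adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * g[[nm]]
          adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * g[[nm]]^2
          params[[nm]] <- params[[nm]] -
            learning_rate * corr * adam_m[[nm]] / (sqrt(adam_v[[nm]]) + eps)
        }
      }
      trace[ep] <- tot / length(train_idx)
      if (ep >= avg_from) {
        avg_n <- avg_n + 1L
        avg_params <- if (is.null(avg_params)) params
                      else purrr::map2(avg_params, params, `+`)
      }
      if (length(val_idx)) {
        v <- val_scorer(params)
        if (v < best_val) {
          best_val <- v
          best_params <- params
        }
      }
    }
    avg_params <- lapply(avg_params, function(p) p / avg_n)
    if (length(val_idx)) {
      avg_val <- val_scorer(avg_params)
      if (avg_val < best_val) {
        best_params <- avg_params
        best_val <- avg_val
      }
      list(params = best_params, trace = trace, score = best_val)
    } else {
      list(params = avg_params, trace = trace, score = trace[epochs])
    }
  }

  withr::local_seed(seed)
  restarts <- max(1, restarts)
  if (validation > 0 && restarts > 1) {
    n_val <- max(1L, round(validation * n))
    val_idx <- sort(sample.int(n, n_val))
    train_idx <- setdiff(seq_len(n), val_idx)
  } else {
    val_idx <- integer(0)
    train_idx <- seq_len(n)
  }
  val_scorer <- if (length(val_idx)) make_val_scorer(val_idx)
  r <- 1 / sqrt(h_size + d)
  best <- NULL; best_score <- Inf
  for (rs in seq_len(restarts)) {
    init <- if (rs == 1) {
      list(W = matcher$W, b = matcher$b, unk = matcher$unk)
    } else {
      list(W = matrix(stats::runif(length(matcher$W), -r, r),
                      nrow(matcher$W), ncol(matcher$W)),
           b = rep(c(0, 1, 0, 0), each = h_size),
           unk = numeric(d))
    }
    run <- run_training(init, train_idx, val_idx)
    if (run$score < best_score) {
      best <- run
      best_score <- run$score
    }
  }

  epoch0 <- if (nrow(matcher$loss_trace)) max(matcher$loss_trace$epoch) else 0L
  matcher$W <- best$params$W
  matcher$b <- best$params$b
  matcher$unk <- best$params$unk
  matcher$loss_trace <- dplyr::bind_rows(
    matcher$loss_trace,
    tibble::tibble(epoch = epoch0 + seq_len(epochs), loss = best$trace)
  )
  matcher
}

#' Rank reference questions against a student question
#'
#' Scores every reference with [pair_similarity()], sorts descending
#' (ties by smallest reference id), drops scores at or below the
#' threshold and returns at most three matches — the "up to a maximum of
#' three questions" rule. An empty result means the question was not
#' understood.
#'
#' @param matcher A [siamese_matcher()].
#' @param student_question Non-empty question text.
#' @param references Data frame with columns `id` and `text` (non-empty).
#' @param threshold Probability threshold in `(0, 1)` (default 0.5).
#' @return A tibble with columns `reference_question_id` and
#'   `probability`, 0--3 rows, sorted by descending probability.
#' @export
rank_questions <- function(matcher, student_question, references,
                           threshold = 0.5) {
  references <- tibble::as_tibble(references)
  if (nrow(references) == 0) {
    stop("rank_questions: the reference question list is empty")
  }
  stopifnot(all(c("id", "text") %in% names(references)))
  hq <- encode(matcher, student_question)
  prob <- vapply(references$text, function(txt) {
    exp(-sum(abs(hq - encode(matcher, txt))))
  }, numeric(1), USE.NAMES = FALSE)
  out <- tibble::tibble(reference_question_id = as.character(references$id),
                        probability = prob)
  out <- out[order(-out$probability, out$reference_question_id), ]
  out <- out[out$probability > threshold, , drop = FALSE]
  utils::head(out, 3)
}

#' Rank-k matching accuracy on a labeled test set
#'
#' For each test question, ranks the full reference list by similarity
#' (no threshold — pure ranking) and scores a hit when the true reference
#' appears among the top `k`. Rank-k accuracy is non-decreasing in `k`.
#'
#' @param matcher A [siamese_matcher()].
#' @param testset Data frame with columns `question` and `true_id`.
#' @param references Data frame with columns `id` and `text`; must
#'   contain every `true_id`.
#' @param k Positive integer.
#' @return Accuracy in `[0, 1]`.
#' @export
evaluate_rank_accuracy <- function(matcher, testset, references, k = 1) {
  testset <- tibble::as_tibble(testset)
  references <- tibble::as_tibble(references)
  if (nrow(testset) == 0) stop("evaluate_rank_accuracy: empty test set")
  stopifnot(k >= 1)
  if (!all(testset$true_id %in% references$id)) {
    stop("evaluate_rank_accuracy: some true reference ids are missing ",
         "from the reference list")
  }
  ref_h <- lapply(references$text, function(txt) encode(matcher, txt))
  ids <- as.character(references$id)
  hits <- vapply(seq_len(nrow(testset)), function(j) {
    hq <- encode(matcher, testset$question[j])
    prob <- vapply(ref_h, function(h) exp(-sum(abs(hq - h))), numeric(1))
    topk <- ids[order(-prob, ids)][seq_len(min(k, length(ids)))]
    testset$true_id[j] %in% topk
  }, logical(1))
  mean(hits)
}

#' Read / write labeled question pairs
#'
#' Tab-separated UTF-8 file with one pair per line:
#' `question_a<TAB>question_b<TAB>label` with label 0 or 1, no header.
#'
#' @param path File path.
#' @param pairs Data frame with columns `question_a`, `question_b`,
#'   `equivalent`.
#' @return `read_labeled_pairs` returns the pairs tibble;
#'   `write_labeled_pairs` returns `path` invisibly.
#' @export
read_labeled_pairs <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                           col.names = c("question_a", "question_b",
                                         "equivalent"),
                           colClasses = c("character", "character", "integer"),
                           fileEncoding = "UTF-8")
  if (!all(tab$equivalent %in% c(0L, 1L))) {
    stop("read_labeled_pairs: labels must be 0 or 1")
  }
  tibble::as_tibble(tab)
}

#' @rdname read_labeled_pairs
#' @export
write_labeled_pairs <- function(pairs, path) {
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("question_a", "question_b", "equivalent") %in% names(pairs)))
  utils::write.table(pairs[, c("question_a", "question_b", "equivalent")],
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Save / load a Siamese matcher
#'
#' Persists the full model (vocabulary, embedding matrix, encoder
#' weights, hyperparameters) as a single archive; the round trip is
#' bit-exact.
#'
#' @param matcher A [siamese_matcher()].
#' @param path File path.
#' @return `save_matcher` returns `path` invisibly; `load_matcher`
#'   returns the matcher.
#' @export
save_matcher <- function(matcher, path) {
  stopifnot(inherits(matcher, "siamese_matcher"))
  saveRDS(matcher, path)
  invisible(path)
}

#' @rdname save_matcher
#' @export
load_matcher <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "siamese_matcher"))
  m
}
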