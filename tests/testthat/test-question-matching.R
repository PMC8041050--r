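# embedding trainer ----------------------------------------------------------

small_corpus <- function() {
  c("do you have fever at night", "do you have pyrexia at night",
    "is the fever worse in the evening", "is the pyrexia worse today",
    "do you have cough in the morning", "is the cough worse at night",
    "do you have headache today", "is the headache worse in the evening",
    "the fever started two days ago", "the pyrexia started yesterday",
    "the cough started last week", "the headache started this morning")
}

test_that("embedding training is seeded, shaped, and honors synonym supervision", {
  syn <- tibble::tibble(a = "fever", b = "pyrexia")
  e1 <- train_embeddings(small_corpus(), syn, dimension = 8, seed = 3)
  e2 <- train_embeddings(small_corpus(), syn, dimension = 8, seed = 3)
  expect_identical(e1$vectors, e2$vectors)          # bitwise determinism
  expect_equal(e1$dimension, 8)
  expect_true(all(lengths(apply(e1$vectors, 1, identity, simplify = FALSE)) == 8))

  # synonym pair closer than random word pairs on average
  cos_syn <- word_cosine(e1, "fever", "pyrexia")
  withr::with_seed(5, {
    words <- rownames(e1$vectors)
    rand <- replicate(100, sample(words, 2))
  })
  cos_rand <- mean(vapply(seq_len(ncol(rand)), function(j) {
    word_cosine(e1, rand[1, j], rand[2, j])
  }, numeric(1)))
  expect_gt(cos_syn, cos_rand)

  expect_error(train_embeddings(character(0)), "empty")
  expect_warning(
    train_embeddings(small_corpus(),
                     tibble::tibble(a = "fever", b = "notacorpusword"),
                     dimension = 4, seed = 1),
    "skipping")
})

# siamese encoder ------------------------------------------------------------

test_that("analytic BPTT gradient matches finite differences", {
  emb <- tiny_embedding(paste0("w", 1:10), dimension = 4, seed = 21)
  m <- siamese_matcher(emb, hidden_size = 3, max_len = 6, seed = 22)
  qa <- "w1 w2 w3"; qb <- "w1 w4 zzz"  # zzz exercises the UNK path
  ns <- asNamespace("vptutor")
  fa <- ns$lstm_forward(m$W, m$b, 3, ns$question_matrix(m, qa)$X, keep_cache = TRUE)
  fb <- ns$lstm_forward(m$W, m$b, 3, ns$question_matrix(m, qb)$X, keep_cache = TRUE)
  diff <- fa$h - fb$h
  s <- exp(-sum(abs(diff)))
  dha <- -2 * (s - 0) * s * sign(diff)
  ga <- ns$lstm_backward(m$W, 3, 4, fa$cache, dha)
  gb <- ns$lstm_backward(m$W, 3, 4, fb$cache, -dha)
  g_an <- ga$dW + gb$dW
  eps <- 1e-6
  for (idx in list(c(1, 1), c(2, 3), c(5, 7), c(12, 2))) {
    mp <- m; mp$W[idx[1], idx[2]] <- mp$W[idx[1], idx[2]] + eps
    mm <- m; mm$W[idx[1], idx[2]] <- mm$W[idx[1], idx[2]] - eps
    g_num <- ((pair_similarity(mp, qa, qb) - 0)^2 -
              (pair_similarity(mm, qa, qb) - 0)^2) / (2 * eps)
    expect_equal(g_an[idx[1], idx[2]], g_num, tolerance = 1e-5)
  }
})

test_that("encoding is deterministic, truncating, and fixed-length", {
  emb <- tiny_embedding(paste0("w", 1:30), dimension = 6, seed = 31)
  m <- siamese_matcher(emb, hidden_size = 5, max_len = 4, seed = 32)
  expect_identical(encode(m, "w1 w2 w3"), encode(m, "w1 w2 w3"))
  long <- paste(paste0("w", 1:10), collapse = " ")
  expect_identical(encode(m, long), encode(m, "w1 w2 w3 w4"))  # first-4 truncation
  h <- encode(m, "w7")
  expect_length(h, 5)
  expect_true(all(is.finite(h)))
  expect_error(encode(m, ""), "empty")
})

test_that("pair similarity is exp(-L1): symmetric, 1 at identity, in (0,1)", {
  emb <- tiny_embedding(paste0("w", 1:40), dimension = 8, seed = 41)
  m <- siamese_matcher(emb, hidden_size = 10, max_len = 12, seed = 42)
  expect_identical(pair_similarity(m, "w1 w2 w9", "w1 w2 w9"), 1)
  withr::with_seed(43, {
    qs <- replicate(100, paste(sample(paste0("w", 1:40), sample(2:8, 1)),
                               collapse = " "))
  })
  for (j in seq(1, 99, by = 2)) {
    s1 <- pair_similarity(m, qs[j], qs[j + 1])
    s2 <- pair_similarity(m, qs[j + 1], qs[j])
    expect_equal(s1, s2, tolerance = 1e-9)
    expect_gt(s1, 0)
    expect_lte(s1, 1)
  }
  # direct consistency with the encoder
  expect_equal(pair_similarity(m, qs[1], qs[2]),
               exp(-sum(abs(encode(m, qs[1]) - encode(m, qs[2])))))
})

test_that("training overfits a tiny separable set and is reproducible", {
  emb <- tiny_embedding(paste0("w", 1:20), dimension = 8, seed = 51)
  m <- siamese_matcher(emb, hidden_size = 8, max_len = 10, seed = 52)
  prs <- tibble::tibble(
    question_a = c("w1 w2 w3", "w2 w3 w4", "w3 w4 w5", "w4 w5 w6", "w5 w6 w7",
                   "w1 w3 w5", "w2 w4 w6", "w3 w5 w7", "w4 w6 w8", "w5 w7 w9"),
    question_b = c("w1 w2 w3", "w2 w3 w4", "w3 w4 w5", "w4 w5 w6", "w5 w6 w7",
                   "w6 w8 w10", "w7 w9 w11", "w8 w10 w12", "w9 w11 w13",
                   "w10 w12 w14"),
    equivalent = c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0))
  mt <- train_matcher(m, prs, epochs = 200, learning_rate = 0.05, seed = 53,
                      restarts = 1)
  tr <- mt$loss_trace$loss
  expect_lt(tr[length(tr)], 0.05)
  expect_true(all(diff(tr) <= 1e-3))  # non-increasing up to SGD jitter
  mt2 <- train_matcher(m, prs, epochs = 200, learning_rate = 0.05, seed = 53,
                       restarts = 1)
  expect_identical(mt$W, mt2$W)
  expect_identical(mt$loss_trace, mt2$loss_trace)

  # separation: equivalent pairs score higher on average than inequivalent
  sims <- vapply(seq_len(nrow(prs)), function(k) {
    pair_similarity(mt, prs$question_a[k], prs$question_b[k])
  }, numeric(1))
  expect_gt(mean(sims[prs$equivalent == 1]), mean(sims[prs$equivalent == 0]))

  expect_error(train_matcher(m, dplyr::mutate(prs, equivalent = 1)),
               "single class")
  expect_error(train_matcher(m, prs, epochs = 0), "epochs")
})

test_that("labeled pairs round-trip through the tab-separated format", {
  prs <- tibble::tibble(question_a = c("do you have fever", "any cough"),
                        question_b = c("is there pyrexia", "do you have fever"),
                        equivalent = c(1L, 0L))
  p <- tempfile(fileext = ".tsv")
  write_labeled_pairs(prs, p)
  expect_equal(read_labeled_pairs(p), prs)
  bad <- tempfile(); writeLines("a\tb\t2", bad)
  expect_error(read_labeled_pairs(bad), "0 or 1")
})

test_that("model persistence round-trips bit-exactly", {
  emb <- tiny_embedding(paste0("w", 1:10), dimension = 4, seed = 61)
  m <- siamese_matcher(emb, hidden_size = 4, max_len = 8, seed = 62)
  p <- tempfile(fileext = ".rds")
  save_matcher(m, p)
  m2 <- load_matcher(p)
  expect_identical(m, m2)
})

# ranking --------------------------------------------------------------------

test_that("the ranker applies the threshold and the max-3 rule", {
  emb <- tiny_embedding(c(paste0("w", 1:10), "ask"), dimension = 6, seed = 71)
  m <- siamese_matcher(emb, hidden_size = 6, max_len = 8, seed = 72)
  query <- "ask w1 w2"
  refs <- tibble::tibble(
    id = sprintf("r%02d", 1:10),
    # five verbatim copies score exactly 1; five distinct texts score less
    text = c(rep(query, 5), paste("w9 w8", paste0("w", 3:7)))
  )
  out <- rank_questions(m, query, refs, threshold = 0.5)
  expect_equal(nrow(out), 3)
  expect_true(all(out$probability > 0.5))
  expect_true(all(diff(out$probability) <= 0))
  # ties at probability 1 resolve to smallest ids
  expect_equal(out$reference_question_id, c("r01", "r02", "r03"))

  # nothing above an impossible threshold -> empty (a valid outcome)
  out2 <- rank_questions(m, "w3 w4", refs[6:10, ], threshold = 0.999999)
  expect_equal(nrow(out2), 0)
  # exactly one above threshold
  out3 <- rank_questions(m, query, refs[5:10, ], threshold = 0.5)
  expect_gte(nrow(out3), 1)
  expect_equal(out3$reference_question_id[1], "r05")
  expect_error(rank_questions(m, query, refs[0, ]), "empty")
})

test_that("rank-k accuracy is 1 for verbatim queries and monotone in k", {
  emb <- tiny_embedding(paste0("w", 1:20), dimension = 6, seed = 81)
  m <- siamese_matcher(emb, hidden_size = 6, max_len = 8, seed = 82)
  refs <- tibble::tibble(id = sprintf("r%d", 1:6),
                         text = paste("w1", paste0("w", 2:7), "w10"))
  verbatim <- tibble::tibble(question = refs$text, true_id = refs$id)
  expect_equal(evaluate_rank_accuracy(m, verbatim, refs, k = 1), 1)
  scrambled <- tibble::tibble(question = paste(refs$text, "w19"),
                              true_id = refs$id)
  a1 <- evaluate_rank_accuracy(m, scrambled, refs, k = 1)
  a3 <- evaluate_rank_accuracy(m, scrambled, refs, k = 3)
  expect_gte(a3, a1)
  expect_equal(evaluate_rank_accuracy(m, scrambled, refs, k = nrow(refs)), 1)
  expect_error(evaluate_rank_accuracy(m, verbatim[0, ], refs, k = 1), "empty")
  expect_error(
    evaluate_rank_accuracy(m, tibble::tibble(question = "w1", true_id = "nope"),
                           refs, k = 1),
    "missing")
})
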