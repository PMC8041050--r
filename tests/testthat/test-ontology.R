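test_that("token normalization lower-cases, strips punctuation, drops stop words", {
  expect_setequal(normalize_tokens("The patient has fever",
                                   stopwords = c("the", "has")),
                  c("patient", "fever"))
  expect_identical(normalize_tokens(""), character(0))
  expect_identical(normalize_tokens("Fever, fever!", stopwords = character(0)),
                   "fever")
})

test_that("Jaccard similarity follows the set definition", {
  expect_equal(jaccard(c("fever", "high"), c("fever", "high")), 1)
  expect_equal(jaccard("fever", "cough"), 0)
  expect_equal(jaccard(c("chest", "pain", "acute"), c("chest", "pain")), 2 / 3)
  expect_equal(jaccard(character(0), character(0)), 0)
  # symmetry, and 1 iff equal non-empty sets
  withr::with_seed(11, {
    pool <- paste0("tok", 1:12)
    for (i in 1:50) {
      a <- sample(pool, sample(1:6, 1))
      b <- sample(pool, sample(1:6, 1))
      expect_equal(jaccard(a, b), jaccard(b, a))
      expect_equal(jaccard(a, b) == 1, setequal(a, b))
    }
  })
})

test_that("concept matching maximizes Jaccard over labels and synonyms", {
  ont <- toy_clinical_ontology()
  m <- match_concept("lung inflammation", ont)
  expect_equal(m$concept_id, "pneumonia")
  expect_equal(m$similarity, 1)
  expect_true(is.na(match_concept("zzz qqq", ont, min_sim = 0.2)$concept_id))
  expect_error(match_concept("fever", ontology(
    tibble::tibble(id = character(0), label = character(0),
                   synonyms = list()),
    tibble::tibble(child = character(0), parent = character(0)))),
    "empty")
})

test_that("concept-match ties break on the lexicographically smallest id", {
  concepts <- tibble::tibble(
    id = c("b2", "a9", "c1"),
    label = c("acute chest pain", "acute chest ache", "knee pain"),
    synonyms = list(character(0), character(0), character(0))
  )
  ont <- ontology(concepts, tibble::tibble(child = character(0),
                                           parent = character(0)),
                  stopwords = character(0))
  # brute-force all similarities for the query and find the tied argmaxes
  q <- normalize_tokens("acute chest", character(0))
  sims <- vapply(seq_len(nrow(concepts)), function(i) {
    jaccard(normalize_tokens(concepts$label[i], character(0)), q)
  }, numeric(1))
  tied <- concepts$id[sims == max(sims)]
  expect_length(tied, 2)
  expect_equal(match_concept("acute chest", ont)$concept_id, min(tied))
})

test_that("path distance is BFS edge count, symmetric, Inf when disconnected", {
  chain <- make_chain_ontology(4)
  expect_equal(path_distance(chain, "c01", "c01"), 0)
  expect_equal(path_distance(chain, "c01", "c02"), 1)
  expect_equal(path_distance(chain, "c01", "c04"), 3)
  expect_error(path_distance(chain, "c01", "nope"), "unknown concept")

  # disconnected component
  conc <- tibble::tibble(id = c("x", "y"), label = c("xx", "yy"),
                         synonyms = list(character(0), character(0)))
  ont2 <- ontology(conc, tibble::tibble(child = character(0),
                                        parent = character(0)))
  expect_identical(path_distance(ont2, "x", "y"), Inf)
})

test_that("distances match an independent BFS oracle on a random DAG", {
  withr::with_seed(42, {
    n <- 50
    ids <- sprintf("n%02d", 1:n)
    # random DAG: each non-root picks 1-2 parents among earlier nodes
    edges <- dplyr::bind_rows(lapply(2:n, function(i) {
      k <- sample(1:min(2, i - 1), 1)
      tibble::tibble(child = ids[i], parent = sample(ids[seq_len(i - 1)], k))
    }))
  })
  conc <- tibble::tibble(id = ids, label = paste0("lab", ids),
                         synonyms = replicate(n, character(0), simplify = FALSE))
  ont <- ontology(conc, edges)
  withr::with_seed(43, {
    pairs <- cbind(sample(ids, 40, replace = TRUE),
                   sample(ids, 40, replace = TRUE))
  })
  for (r in seq_len(nrow(pairs))) {
    d <- path_distance(ont, pairs[r, 1], pairs[r, 2])
    expect_equal(d, bfs_oracle(edges, ids, pairs[r, 1], pairs[r, 2]))
    expect_equal(d, path_distance(ont, pairs[r, 2], pairs[r, 1]))
  }
  # triangle inequality on a sample of triples
  withr::with_seed(44, trip <- replicate(30, sample(ids, 3)))
  for (c_ in seq_len(ncol(trip))) {
    dxz <- path_distance(ont, trip[1, c_], trip[3, c_])
    dxy <- path_distance(ont, trip[1, c_], trip[2, c_])
    dyz <- path_distance(ont, trip[2, c_], trip[3, c_])
    expect_lte(dxz, dxy + dyz)
  }
})

test_that("hypothesis verdicts partition distances 0..10 and Inf exhaustively", {
  chain <- make_chain_ontology(12)
  for (d in 0:10) {
    res <- classify_hypothesis(sprintf("disorderx%02d", d + 1), "c01", chain)
    expect_equal(res$distance, d)
    expect_equal(res$verdict,
                 if (d == 0) "correct" else if (d <= 4) "close" else "incorrect")
  }
  # disconnected -> incorrect; unmatched -> unrecognized
  conc <- dplyr::bind_rows(chain$concepts,
                           tibble::tibble(id = "iso", label = "isolatedx",
                                          synonyms = list(character(0))))
  ont <- ontology(conc, chain$edges)
  iso <- classify_hypothesis("isolatedx", "c01", ont)
  expect_equal(iso$verdict, "incorrect")
  expect_identical(iso$distance, Inf)
  expect_equal(classify_hypothesis("qqq zzz", "c01", chain)$verdict,
               "unrecognized")
  expect_error(classify_hypothesis("disorderx01", character(0), chain),
               "empty")
})

test_that("ancestor queries follow parent links upward and are irreflexive", {
  ont <- toy_clinical_ontology()
  expect_true(is_ancestor(ont, "pneumonia", "interstitial_pneumonia"))
  expect_true(is_ancestor(ont, "respiratory_disease", "interstitial_pneumonia"))
  expect_false(is_ancestor(ont, "interstitial_pneumonia", "pneumonia"))
  expect_false(is_ancestor(ont, "pneumonia", "pneumonia"))
  # siblings, checked against a brute-force transitive closure
  up <- function(id) {
    anc <- character(0); frontier <- id
    while (length(frontier)) {
      ps <- ont$edges$parent[ont$edges$child %in% frontier]
      ps <- setdiff(ps, anc)
      anc <- c(anc, ps); frontier <- ps
    }
    anc
  }
  expect_false(is_ancestor(ont, "pharyngitis", "tonsillitis"))
  for (a in ont$concepts$id) {
    for (b in c("interstitial_pneumonia", "pharyngitis")) {
      expect_equal(is_ancestor(ont, a, b), a %in% up(b))
    }
  }
})

test_that("ontology files round-trip, and bad edge lists are rejected", {
  ont <- toy_clinical_ontology()
  tc <- tempfile(); te <- tempfile()
  write_ontology(ont, tc, te)
  ont2 <- read_ontology(tc, te)
  expect_equal(ont2$concepts$id, ont$concepts$id)
  expect_equal(ont2$concepts$synonyms, ont$concepts$synonyms)
  expect_equal(path_distance(ont2, "pharyngitis", "pneumonia"), 4)

  # the shipped fixture copies load identically
  shipped <- read_ontology(
    system.file("extdata", "toy_clinical_concepts.tsv", package = "vptutor"),
    system.file("extdata", "toy_clinical_edges.tsv", package = "vptutor"))
  expect_equal(shipped$concepts$label, ont$concepts$label)

  cyc <- tibble::tibble(child = c("a", "b"), parent = c("b", "a"))
  conc <- tibble::tibble(id = c("a", "b"), label = c("aa", "bb"),
                         synonyms = list(character(0), character(0)))
  expect_error(ontology(conc, cyc), "cycle")
  expect_error(ontology(conc, tibble::tibble(child = "a", parent = "zz")),
               "unknown concept")
  expect_error(ontology(conc, tibble::tibble(child = "a", parent = "a")),
               "own parent")
})
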