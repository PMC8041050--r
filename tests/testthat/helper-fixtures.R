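# fixtures built in code: chain ontology, tiny deterministic matcher,
# independent graph oracles used to cross-check the implementation.

# linear chain c01 - c02 - ... - cNN, each concept the sole parent of the
# next; labels are single unique tokens so Jaccard matching is exact
make_chain_ontology <- function(n) {
  ids <- sprintf("c%02d", seq_len(n))
  concepts <- tibble::tibble(id = ids,
                             label = sprintf("disorderx%02d", seq_len(n)),
                             synonyms = replicate(n, character(0),
                                                  simplify = FALSE))
  edges <- tibble::tibble(child = ids[-1], parent = ids[-n])
  ontology(concepts, edges)
}

# deterministic word vectors over a fixed vocabulary; rows unit-norm with a
# spread-out random basis so distinct words encode differently
tiny_embedding <- function(words, dimension = 12, seed = 99) {
  withr::with_seed(seed, {
    V <- matrix(stats::rnorm(length(words) * dimension), length(words),
                dimension, dimnames = list(words, NULL))
  })
  embedding_model(V / sqrt(rowSums(V^2)))
}

case_vocabulary <- function(case) {
  texts <- c(case$scenario, case$questions$text, case$questions$answer,
             case$exams$name, case$tests$name, unlist(case$exams$synonyms),
             unlist(case$tests$synonyms))
  unique(unlist(lapply(texts, vptutor:::question_tokens)))
}

# untrained matcher whose encodings are deterministic; with threshold just
# below 1 only (near-)verbatim questions match, which is all the engine
# tests need
table1_matcher <- function(case = table1_case()) {
  emb <- tiny_embedding(case_vocabulary(case))
  siamese_matcher(emb, hidden_size = 16, max_len = 20, seed = 7)
}

counter_clock <- function() {
  i <- 0L
  function() {
    i <<- i + 1L
    sprintf("t%04d", i)
  }
}

# independent breadth-first-search oracle over an explicit adjacency list
bfs_oracle <- function(edges, ids, from, to) {
  adj <- stats::setNames(replicate(length(ids), character(0),
                                   simplify = FALSE), ids)
  for (k in seq_len(nrow(edges))) {
    a <- edges$child[k]; b <- edges$parent[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  dist <- stats::setNames(rep(Inf, length(ids)), ids)
  dist[from] <- 0
  frontier <- from
  while (length(frontier)) {
    nxt <- character(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  unname(dist[to])
}

# brute-force likelihood over all 2^T hidden paths of the two-state model
bkt_brute_likelihood <- function(params, obs) {
  T_ <- length(obs)
  tot <- 0
  for (m in 0:(2^T_ - 1)) {
    path <- as.integer(intToBits(m))[seq_len(T_)] # 0 unknown, 1 known
    pr <- if (path[1] == 1) params$p_L0 else 1 - params$p_L0
    for (t in seq_len(T_)) {
      e <- if (path[t] == 1) {
        if (obs[t] == 1) 1 - params$p_S else params$p_S
      } else {
        if (obs[t] == 1) params$p_G else 1 - params$p_G
      }
      pr <- pr * e
      if (t < T_) {
        a <- if (path[t] == 0 && path[t + 1] == 0) 1 - params$p_T
        else if (path[t] == 0 && path[t + 1] == 1) params$p_T
        else if (path[t] == 1 && path[t + 1] == 1) 1
        else 0
        pr <- pr * a
      }
      if (pr == 0) break
    }
    tot <- tot + pr
  }
  tot
}

# pooled rank-k accuracy over the per-simulation reference lists
benchmark_accuracy <- function(matcher, bench, k) {
  hits <- vapply(unique(bench$test$simulation), function(s) {
    refs <- bench$references[bench$references$simulation == s, ]
    ts <- bench$test[bench$test$simulation == s, ]
    evaluate_rank_accuracy(
      matcher, tibble::tibble(question = ts$question, true_id = ts$true_id),
      refs[, c("id", "text")], k = k) * nrow(ts)
  }, numeric(1))
  sum(hits) / nrow(bench$test)
}
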