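#' Build a concept ontology
#'
#' Constructs the ontology object used for hypothesis matching: a table of
#' concepts (id, preferred label, synonyms) and an is-a edge list
#' (child -> parent). The is-a relation must be acyclic; path distance is
#' measured on the undirected graph.
#'
#' @param concepts A data frame with columns `id` (unique, non-empty
#'   character), `label` (non-empty character) and `synonyms` — either a
#'   list-column of character vectors or a character column of
#'   pipe-separated synonyms (`""` for none).
#' @param edges A data frame with columns `child` and `parent` (concept
#'   ids). A concept may have several parents; no concept may be its own
#'   parent.
#' @param stopwords Stop words used when pre-tokenizing labels and
#'   synonyms for Jaccard matching.
#' @return An object of class `ontology`.
#' @seealso [read_ontology()], [make_toy_ontology()], [path_distance()],
#'   [match_concept()]
#' @export
ontology <- function(concepts, edges, stopwords = default_stopwords()) {
  concepts <- tibble::as_tibble(concepts)
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("id", "label") %in% names(concepts)))
  if (!"synonyms" %in% names(concepts)) concepts$synonyms <- list(character(0))
  if (is.character(concepts$synonyms)) {
    concepts$synonyms <- lapply(concepts$synonyms, function(s) {
      if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, "|", fixed = TRUE)[[1]]
    })
  }
  concepts$id <- as.character(concepts$id)
  if (anyDuplicated(concepts$id)) {
    stop("ontology: duplicated concept ids: ",
         paste(unique(concepts$id[duplicated(concepts$id)]), collapse = ", "))
  }
  if (any(!nzchar(concepts$label) | is.na(concepts$label))) {
    stop("ontology: every concept needs a non-empty label")
  }
  if (nrow(edges)) {
    edges$child <- as.character(edges$child)
    edges$parent <- as.character(edges$parent)
    missing <- setdiff(unique(c(edges$child, edges$parent)), concepts$id)
    if (length(missing)) {
      stop("ontology: edge references unknown concept id(s): ",
           paste(missing, collapse = ", "))
    }
    if (any(edges$child == edges$parent)) {
      stop("ontology: a concept cannot be its own parent")
    }
  }

  # directed graph child -> parent for ancestor queries and the acyclicity
  # check; distances use its undirected view
  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent")],
    directed = TRUE,
    vertices = concepts$id
  )
  if (!igraph::is_dag(g)) stop("ontology: the is-a relation contains a cycle")

  # pre-tokenized texts (label + each synonym) for Jaccard matching
  token_sets <- purrr::map2(concepts$label, concepts$synonyms, function(lab, syn) {
    lapply(c(lab, syn), normalize_tokens, stopwords = stopwords)
  })

  structure(
    list(concepts = concepts, edges = edges, graph = g,
         token_sets = token_sets, stopwords = stopwords),
    class = "ontology"
  )
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d concepts, %d is-a edges\n",
              nrow(x$concepts), nrow(x$edges)))
  invisible(x)
}

#' Read an ontology from concept and edge files
#'
#' Concepts are tab-separated `(id, label, synonyms)` with synonyms
#' pipe-separated (empty for none); edges are tab-separated
#' `(child_id, parent_id)`. Both files are header-less UTF-8. Acyclicity is
#' validated on load. (An adapter for licensed terminology releases can be
#' written against [ontology()]; no licensed data ships with the package.)
#'
#' @param concepts_file,edges_file File paths.
#' @param stopwords Stop-word list, as in [ontology()].
#' @return An `ontology` object.
#' @export
read_ontology <- function(concepts_file, edges_file,
                          stopwords = default_stopwords()) {
  con <- utils::read.delim(concepts_file, header = FALSE, sep = "\t",
                           quote = "", col.names = c("id", "label", "synonyms"),
                           colClasses = "character", fileEncoding = "UTF-8")
  edg <- if (file.size(edges_file) > 0) {
    utils::read.delim(edges_file, header = FALSE, sep = "\t", quote = "",
                      col.names = c("child", "parent"),
                      colClasses = "character", fileEncoding = "UTF-8")
  } else {
    tibble::tibble(child = character(0), parent = character(0))
  }
  ontology(con, edg, stopwords = stopwords)
}

#' Write an ontology to concept and edge files
#'
#' Inverse of [read_ontology()]: header-less tab-separated UTF-8 files,
#' synonyms pipe-separated.
#'
#' @param ont An [ontology()].
#' @param concepts_file,edges_file Output paths.
#' @return A character vector of the two paths, invisibly.
#' @export
write_ontology <- function(ont, concepts_file, edges_file) {
  stopifnot(inherits(ont, "ontology"))
  syn <- vapply(ont$concepts$synonyms, paste, character(1), collapse = "|")
  utils::write.table(cbind(ont$concepts$id, ont$concepts$label, syn),
                     concepts_file, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  utils::write.table(ont$edges, edges_file, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(c(concepts_file, edges_file))
}

check_concept_ids <- function(ont, ids) {
  missing <- setdiff(ids, ont$concepts$id)
  if (length(missing)) {
    stop("unknown concept id(s): ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Shortest-path distance between two concepts
#'
#' The minimum number of edges in any path connecting the two nodes of the
#' (undirected) is-a graph; `Inf` when the concepts are disconnected.
#' Symmetric by construction.
#'
#' @param ont An [ontology()].
#' @param c1,c2 Concept ids.
#' @return A non-negative number of edges, or `Inf`.
#' @export
path_distance <- function(ont, c1, c2) {
  stopifnot(inherits(ont, "ontology"))
  check_concept_ids(ont, c(c1, c2))
  d <- igraph::distances(ont$graph, v = c1, to = c2, mode = "all")[1, 1]
  unname(d)
}

#' Is concept `a` an ancestor of concept `b`?
#'
#' TRUE iff `a` is reachable from `b` by following parent links upward.
#' Irreflexive: `is_ancestor(ont, c, c)` is FALSE.
#'
#' @param ont An [ontology()].
#' @param a,b Concept ids.
#' @return Logical scalar.
#' @export
is_ancestor <- function(ont, a, b) {
  stopifnot(inherits(ont, "ontology"))
  check_concept_ids(ont, c(a, b))
  if (a == b) return(FALSE)
  up <- igraph::subcomponent(ont$graph, v = b, mode = "out")
  a %in% setdiff(names(up), b)
}

#' Match free text to the best ontology concept
#'
#' Scores the input against every concept's label and every synonym by
#' Jaccard similarity over normalized token sets and returns the best
#' concept. Ties are broken by the lexicographically smallest concept id.
#' When the best similarity falls below `min_sim` the match is absent
#' (`NA`), which downstream code treats as "unrecognized — please
#' rephrase".
#'
#' @param text Free text.
#' @param ont An [ontology()]; must be non-empty.
#' @param min_sim Minimum acceptable similarity in `[0, 1]` (default 0.2).
#' @return A one-row tibble with columns `concept_id` (character or `NA`)
#'   and `similarity`.
#' @export
match_concept <- function(text, ont, min_sim = 0.2) {
  stopifnot(inherits(ont, "ontology"))
  if (nrow(ont$concepts) == 0) stop("match_concept: the ontology is empty")
  toks <- normalize_tokens(text, ont$stopwords)
  sims <- vapply(ont$token_sets, function(sets) {
    max(vapply(sets, jaccard, numeric(1), b = toks))
  }, numeric(1))
  best <- max(sims)
  if (best < min_sim) {
    return(tibble::tibble(concept_id = NA_character_, similarity = best))
  }
  cand <- ont$concepts$id[sims == best]
  tibble::tibble(concept_id = min(cand), similarity = best)
}

#' Classify a free-text diagnostic hypothesis against reference hypotheses
#'
#' The hypothesis text is first linked to its best-matching ontology
#' concept ([match_concept()]); the graph path distance to each reference
#' hypothesis is then computed and the minimum taken. The verdict follows
#' the published banding: distance 0 is `correct`, 1--4 is `close`, 5 or
#' more (or disconnected) is `incorrect`; when no concept reaches
#' `min_sim` the verdict is `unrecognized`.
#'
#' @param text Free-text hypothesis.
#' @param references Character vector of reference concept ids (non-empty,
#'   all present in `ont`).
#' @param ont An [ontology()].
#' @param min_sim Minimum Jaccard similarity for concept linking.
#' @return A one-row tibble: `matched_concept_id`, `nearest_reference_id`,
#'   `distance`, `verdict` (factor-free character, one of
#'   `correct`/`close`/`incorrect`/`unrecognized`) and `similarity`.
#' @export
classify_hypothesis <- function(text, references, ont, min_sim = 0.2) {
  stopifnot(inherits(ont, "ontology"))
  if (length(references) == 0) {
    stop("classify_hypothesis: the reference hypothesis list is empty")
  }
  check_concept_ids(ont, references)
  m <- match_concept(text, ont, min_sim = min_sim)
  if (is.na(m$concept_id)) {
    return(tibble::tibble(
      matched_concept_id = NA_character_, nearest_reference_id = NA_character_,
      distance = Inf, verdict = "unrecognized", similarity = m$similarity
    ))
  }
  d <- igraph::distances(ont$graph, v = m$concept_id, to = references,
                         mode = "all")[1, ]
  dmin <- min(d)
  nearest <- min(references[d == dmin])
  verdict <- if (dmin == 0) "correct" else if (dmin <= 4) "close" else "incorrect"
  tibble::tibble(
    matched_concept_id = m$concept_id, nearest_reference_id = nearest,
    distance = unname(dmin), verdict = verdict, similarity = m$similarity
  )
}
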