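#' Construct a clinical case
#'
#' A clinical case is the tutor-authored reference content for one
#' simulation: the presenting scenario, the reference anamnestic
#' questions with their answers, the reference physical exams and medical
#' tests with findings, the diagnostic factors each of these reveals, the
#' reference diagnostic hypotheses, the
#' increase/decrease/no-effect (I/D/N) reference grid over factors x
#' hypotheses, the final diagnosis and per-hypothesis review links.
#'
#' All invariants are checked here (and therefore on [load_case()]):
#' unique ids, closed modality set, grid labels in `{I, D, N}`, grid
#' covering exactly the factor x hypothesis cross product, every revealed
#' factor existing, and the final diagnosis among the hypotheses.
#'
#' @param scenario Scenario text shown at the start.
#' @param factors Tibble `(id, name, value, modality)`, modality one of
#'   `scenario`, `anamnesis`, `physical_exam`, `medical_test`.
#' @param questions Tibble `(id, text, answer, factors)`; `factors` is a
#'   list-column of revealed factor ids.
#' @param exams,tests Tibbles `(id, name, synonyms, finding, factors)`;
#'   `synonyms` and `factors` are list-columns.
#' @param hypotheses Character vector of reference hypothesis concept
#'   ids.
#' @param grid Tibble `(factor, hypothesis, label)` with labels in
#'   `{I, D, N}`.
#' @param final_diagnosis A member of `hypotheses`.
#' @param review_links Named character vector or list mapping hypothesis
#'   id to a review-topic URL (may be empty).
#' @return An object of class `clinical_case`.
#' @export
clinical_case <- function(scenario, factors, questions, exams, tests,
                          hypotheses, grid, final_diagnosis,
                          review_links = character(0)) {
  factors <- tibble::as_tibble(factors)
  questions <- normalize_revealers(questions, need_answer = TRUE)
  exams <- normalize_revealers(exams, need_answer = FALSE)
  tests <- normalize_revealers(tests, need_answer = FALSE)
  grid <- tibble::as_tibble(grid)
  hypotheses <- as.character(hypotheses)
  review_links <- unlist(review_links)
  if (is.null(review_links)) review_links <- character(0)

  fail <- function(field, msg) {
    stop(sprintf("invalid clinical case (field '%s'): %s", field, msg))
  }
  if (!is.character(scenario) || length(scenario) != 1 || !nzchar(scenario)) {
    fail("scenario", "must be a non-empty string")
  }
  if (!all(c("id", "name", "value", "modality") %in% names(factors)) ||
      nrow(factors) == 0) {
    fail("factors", "need columns id, name, value, modality and >= 1 row")
  }
  if (anyDuplicated(factors$id)) fail("factors", "duplicated factor ids")
  bad_mod <- setdiff(factors$modality,
                     c("scenario", "anamnesis", "physical_exam", "medical_test"))
  if (length(bad_mod)) fail("factors", paste("unknown modality:", bad_mod[1]))
  for (nm in c("questions", "exams", "tests")) {
    tab <- get(nm)
    if (anyDuplicated(tab$id)) fail(nm, "duplicated ids")
    unknown <- setdiff(unlist(tab$factors), factors$id)
    if (length(unknown)) {
      fail(nm, paste("revealed factor id(s) not defined:",
                     paste(unknown, collapse = ", ")))
    }
  }
  if (length(hypotheses) == 0) fail("hypotheses", "need >= 1 hypothesis")
  if (anyDuplicated(hypotheses)) fail("hypotheses", "duplicated hypothesis ids")
  if (!all(c("factor", "hypothesis", "label") %in% names(grid))) {
    fail("grid", "need columns factor, hypothesis, label")
  }
  if (!all(grid$label %in% c("I", "D", "N"))) {
    fail("grid", "labels must be I, D or N")
  }
  want <- tidyr::expand_grid(factor = factors$id, hypothesis = hypotheses)
  have <- grid[, c("factor", "hypothesis")]
  missing_cells <- dplyr::anti_join(want, have, by = c("factor", "hypothesis"))
  extra_cells <- dplyr::anti_join(have, want, by = c("factor", "hypothesis"))
  if (nrow(missing_cells)) {
    fail("grid", paste("missing cell(s):",
                       paste(missing_cells$factor, missing_cells$hypothesis,
                             sep = "/", collapse = ", ")))
  }
  if (nrow(extra_cells) || anyDuplicated(have)) {
    fail("grid", "cells outside the factor x hypothesis cross product or duplicated")
  }
  if (length(final_diagnosis) != 1 || !final_diagnosis %in% hypotheses) {
    fail("final_diagnosis", "must be exactly one of the reference hypotheses")
  }
  if (length(review_links) && length(setdiff(names(review_links), hypotheses))) {
    fail("review_links", "keys must be hypothesis ids")
  }

  structure(
    list(scenario = scenario, factors = factors, questions = questions,
         exams = exams, tests = tests, hypotheses = hypotheses,
         grid = grid, final_diagnosis = as.character(final_diagnosis),
         review_links = review_links),
    class = "clinical_case"
  )
}

normalize_revealers <- function(tab, need_answer) {
  tab <- tibble::as_tibble(tab)
  cols <- if (need_answer) c("id", "text", "answer", "factors")
          else c("id", "name", "synonyms", "finding", "factors")
  missing <- setdiff(cols, names(tab))
  if (length(missing)) {
    stop(sprintf("invalid clinical case: missing column(s) %s",
                 paste(missing, collapse = ", ")))
  }
  tab$id <- as.character(tab$id)
  if (!need_answer && !is.list(tab$synonyms)) {
    tab$synonyms <- lapply(tab$synonyms, function(s) {
      if (is.null(s) || is.na(s) || !nzchar(s)) character(0)
      else strsplit(s, "|", fixed = TRUE)[[1]]
    })
  }
  if (!is.list(tab$factors)) tab$factors <- as.list(tab$factors)
  tab$factors <- lapply(tab$factors, as.character)
  tab[, cols]
}

#' @export
print.clinical_case <- function(x, ...) {
  cat(sprintf(paste0("<clinical_case> %d factors, %d questions, %d exams, ",
                     "%d tests, %d hypotheses (final: %s)\n"),
              nrow(x$factors), nrow(x$questions), nrow(x$exams),
              nrow(x$tests), length(x$hypotheses), x$final_diagnosis))
  invisible(x)
}

#' Load a clinical case from its JSON definition
#'
#' The case schema is a JSON object with keys `scenario` (string),
#' `factors` (array of `{id, name, value, modality}`), `questions`
#' (array of `{id, text, answer, factors}`), `exams` and `tests` (arrays
#' of `{id, name, synonyms, finding, factors}`), `hypotheses` (array of
#' concept ids), `grid` (array of `{factor, hypothesis, label}`),
#' `final_diagnosis` (string) and `review_links` (object hypothesis ->
#' URL). Validation errors name the offending field.
#'
#' @param path Path to the JSON case file.
#' @return A [clinical_case()].
#' @seealso [write_case()] for the inverse.
#' @export
load_case <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  need <- c("scenario", "factors", "questions", "exams", "tests",
            "hypotheses", "grid", "final_diagnosis")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("invalid clinical case: missing top-level field(s): ",
         paste(missing, collapse = ", "))
  }
  arr <- function(entries, fields, listcols = character(0)) {
    if (length(entries) == 0) {
      out <- lapply(fields, function(f) {
        if (f %in% listcols) list() else character(0)
      })
      names(out) <- fields
      return(tibble::as_tibble(out))
    }
    rows <- lapply(entries, function(e) {
      out <- lapply(fields, function(f) {
        v <- e[[f]]
        if (f %in% listcols) list(as.character(unlist(v)))
        else if (is.null(v)) NA_character_
        else as.character(v)
      })
      names(out) <- fields
      tibble::as_tibble(out)
    })
    dplyr::bind_rows(rows)
  }
  clinical_case(
    scenario = as.character(raw$scenario),
    factors = arr(raw$factors, c("id", "name", "value", "modality")),
    questions = arr(raw$questions, c("id", "text", "answer", "factors"),
                    listcols = "factors"),
    exams = arr(raw$exams, c("id", "name", "synonyms", "finding", "factors"),
                listcols = c("synonyms", "factors")),
    tests = arr(raw$tests, c("id", "name", "synonyms", "finding", "factors"),
                listcols = c("synonyms", "factors")),
    hypotheses = as.character(unlist(raw$hypotheses)),
    grid = arr(raw$grid, c("factor", "hypothesis", "label")),
    final_diagnosis = as.character(raw$final_diagnosis),
    review_links = unlist(raw$review_links)
  )
}

#' Write a clinical case to its JSON definition
#'
#' @param case A [clinical_case()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_case <- function(case, path) {
  stopifnot(inherits(case, "clinical_case"))
  tab2list <- function(tab) {
    lapply(seq_len(nrow(tab)), function(i) {
      row <- as.list(tab[i, ])
      lapply(row, function(v) if (is.list(v)) unlist(v) %||% character(0) else v)
    })
  }
  obj <- list(
    scenario = case$scenario,
    factors = tab2list(case$factors),
    questions = tab2list(case$questions),
    exams = tab2list(case$exams),
    tests = tab2list(case$tests),
    hypotheses = case$hypotheses,
    grid = tab2list(case$grid),
    final_diagnosis = case$final_diagnosis,
    review_links = as.list(case$review_links)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
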