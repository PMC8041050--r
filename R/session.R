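#' Start a simulation session on a clinical case
#'
#' A session holds the mutable student state of one simulation: the
#' diagnostic factors gathered so far, the differential diagnosis, the
#' submitted binary grids and pattern links, and an append-only action
#' log. Session operations take the session first and return the updated
#' session, so they chain with the pipe; the result of the most recent
#' operation is in `session$last` and every operation is appended to
#' `session$log`. The student may move freely between data gathering and
#' data analysis until [select_final_diagnosis()] closes the session.
#'
#' @param case A [clinical_case()].
#' @param ontology The [ontology()] used for hypothesis and exam/test
#'   matching.
#' @param matcher The [siamese_matcher()] used for anamnestic question
#'   matching.
#' @param threshold Question-ranker probability threshold (default 0.5).
#' @param min_sim Minimum Jaccard similarity for concept and exam/test
#'   matching (default 0.2).
#' @param clock A zero-argument function returning the timestamp to log;
#'   injectable so tests and replays are deterministic. Defaults to
#'   [Sys.time()].
#' @return An object of class `vp_session`.
#' @export
new_session <- function(case, ontology, matcher, threshold = 0.5,
                        min_sim = 0.2, clock = Sys.time) {
  stopifnot(inherits(case, "clinical_case"), inherits(ontology, "ontology"))
  check_concept_ids(ontology, c(case$hypotheses, case$final_diagnosis))
  structure(
    list(case = case, ontology = ontology, matcher = matcher,
         threshold = threshold, min_sim = min_sim, clock = clock,
         gathered = character(0), differential = character(0),
         grid_submissions = list(), pattern_links = NULL,
         log = tibble::tibble(step = integer(0), timestamp = character(0),
                              action = character(0), input = character(0),
                              outcome = character(0),
                              feedback_code = character(0),
                              feedback_message = character(0)),
         finished = FALSE, final_choice = NA_character_,
         final_outcome = NA_character_, last = NULL),
    class = "vp_session"
  )
}

#' @export
print.vp_session <- function(x, ...) {
  cat(sprintf(paste0("<vp_session> %d factors gathered, differential {%s}, ",
                     "%d grid submission(s), %d logged action(s)%s\n"),
              length(x$gathered), paste(x$differential, collapse = ", "),
              length(x$grid_submissions), nrow(x$log),
              if (x$finished) sprintf(" — finished (%s)", x$final_outcome) else ""))
  if (!is.null(x$last$feedback)) {
    cat("last feedback:", x$last$feedback$message[1], "\n")
  }
  invisible(x)
}

check_open <- function(session) {
  stopifnot(inherits(session, "vp_session"))
  if (session$finished) {
    stop("the session is finished; start a new simulation to continue")
  }
  invisible(TRUE)
}

log_action <- function(session, action, input, outcome, feedback) {
  ts <- session$clock()
  if (inherits(ts, c("POSIXt", "Date"))) {
    ts <- format(ts, "%Y-%m-%dT%H:%M:%OS6")
  }
  session$log <- dplyr::bind_rows(
    session$log,
    tibble::tibble(step = nrow(session$log) + 1L,
                   timestamp = as.character(ts),
                   action = action, input = input, outcome = outcome,
                   feedback_code = feedback$code[1],
                   feedback_message = feedback$message[1])
  )
  session
}

#' Review the presenting scenario
#'
#' The first data-gathering action: reading the patient record reveals
#' every factor with modality `scenario`.
#'
#' @param session A [new_session()].
#' @return The updated session; `session$last$factors` lists the factors
#'   revealed.
#' @export
review_scenario <- function(session) {
  check_open(session)
  ids <- session$case$factors$id[session$case$factors$modality == "scenario"]
  session$gathered <- union(session$gathered, ids)
  fb <- inner_feedback("scenario_reviewed")
  session$last <- list(action = "review_scenario", factors = ids,
                       scenario = session$case$scenario, feedback = fb)
  log_action(session, "review_scenario", "", "scenario_reviewed", fb)
}

#' Ask the virtual patient an anamnestic question
#'
#' The free-text question is ranked against the case's reference
#' questions by the Siamese matcher ([rank_questions()]): every match
#' above the threshold (at most three) returns its authored answer and
#' reveals its diagnostic factors. No match yields
#' "not understood — please rephrase" feedback. Either way the action is
#' logged.
#'
#' @param session An open [new_session()].
#' @param question Non-empty free-text question.
#' @return The updated session; `session$last$matches` is a tibble
#'   `(reference_question_id, probability, answer)` with 0--3 rows.
#' @export
ask_history <- function(session, question) {
  check_open(session)
  ranked <- rank_questions(session$matcher, question,
                           session$case$questions[, c("id", "text")],
                           threshold = session$threshold)
  if (nrow(ranked) == 0) {
    fb <- inner_feedback("question_unmatched")
    session$last <- list(action = "ask_history",
                         matches = tibble::tibble(reference_question_id = character(0),
                                                  probability = numeric(0),
                                                  answer = character(0)),
                         feedback = fb)
    return(log_action(session, "ask_history", question, "question_unmatched", fb))
  }
  qtab <- session$case$questions
  hit <- match(ranked$reference_question_id, qtab$id)
  revealed <- unique(unlist(qtab$factors[hit]))
  session$gathered <- union(session$gathered, revealed)
  fb <- inner_feedback("question_matched")
  session$last <- list(
    action = "ask_history",
    matches = dplyr::mutate(ranked, answer = qtab$answer[hit]),
    factors = revealed, feedback = fb
  )
  log_action(session, "ask_history", question, "question_matched", fb)
}

#' Request a physical exam or medical test
#'
#' The request is matched by Jaccard token similarity against the names
#' and synonyms of the case's reference exams and tests (short noun
#' phrases, where token overlap is the right tool). A match returns the
#' authored finding and reveals its factors; no match triggers the
#' inner-loop "inappropriate exam" feedback.
#'
#' @param session An open [new_session()].
#' @param request Non-empty free-text exam/test request.
#' @return The updated session; on a match `session$last$finding` holds
#'   the finding text and `session$last$item_id` the matched reference.
#' @export
request_exam_or_test <- function(session, request) {
  check_open(session)
  if (is.na(request) || !nzchar(trimws(request))) {
    stop("request_exam_or_test: empty request; prompt the student for input")
  }
  items <- dplyr::bind_rows(
    dplyr::mutate(session$case$exams, kind = "exam"),
    dplyr::mutate(session$case$tests, kind = "test")
  )
  toks <- normalize_tokens(request, session$ontology$stopwords)
  sims <- vapply(seq_len(nrow(items)), function(i) {
    texts <- c(items$name[i], items$synonyms[[i]])
    max(vapply(texts, function(tx) {
      jaccard(normalize_tokens(tx, session$ontology$stopwords), toks)
    }, numeric(1)))
  }, numeric(1))
  best <- if (length(sims)) max(sims) else 0
  if (best < session$min_sim) {
    fb <- inner_feedback("exam_unmatched")
    session$last <- list(action = "request_exam_or_test", finding = NULL,
                         feedback = fb)
    return(log_action(session, "request_exam_or_test", request,
                      "exam_unmatched", fb))
  }
  i <- which(sims == best)
  i <- i[order(items$id[i])][1]
  session$gathered <- union(session$gathered, items$factors[[i]])
  fb <- inner_feedback("exam_matched")
  session$last <- list(action = "request_exam_or_test",
                       item_id = items$id[i], kind = items$kind[i],
                       finding = items$finding[i],
                       factors = items$factors[[i]], feedback = fb)
  log_action(session, "request_exam_or_test", request, "exam_matched", fb)
}

#' Propose a diagnostic hypothesis in free text
#'
#' The hypothesis is classified against the case's reference hypotheses
#' by ontology matching and path distance ([classify_hypothesis()]):
#' a `correct` hypothesis (distance 0) joins the differential; a `close`
#' hypothesis that is an ancestor of the nearest reference triggers
#' "be more specific" feedback, any other `close` hypothesis a hint
#' toward the closest reference; `incorrect` and `unrecognized`
#' hypotheses are rejected.
#'
#' @param session An open [new_session()].
#' @param text Free-text hypothesis.
#' @return The updated session; `session$last$match` is the
#'   [classify_hypothesis()] row.
#' @export
propose_hypothesis <- function(session, text) {
  check_open(session)
  res <- classify_hypothesis(text, session$case$hypotheses,
                             session$ontology, min_sim = session$min_sim)
  outcome <- switch(
    res$verdict,
    correct = "hypothesis_correct",
    close = if (is_ancestor(session$ontology, res$matched_concept_id,
                            res$nearest_reference_id)) {
      "hypothesis_close_ancestor"
    } else "hypothesis_close",
    incorrect = "hypothesis_incorrect",
    unrecognized = "hypothesis_unrecognized"
  )
  if (outcome == "hypothesis_correct") {
    session$differential <- union(session$differential, res$matched_concept_id)
  }
  payload <- if (outcome %in% c("hypothesis_close", "hypothesis_close_ancestor")) {
    label <- session$ontology$concepts$label[
      session$ontology$concepts$id == res$nearest_reference_id]
    list(nearest_reference_id = res$nearest_reference_id,
         nearest_reference_label = label, distance = res$distance)
  }
  fb <- inner_feedback(outcome, payload)
  session$last <- list(action = "propose_hypothesis", match = res,
                       feedback = fb)
  log_action(session, "propose_hypothesis", text, outcome, fb)
}

#' Build the (empty) binary-analysis grid
#'
#' Generates the table of the binary analysis: one row per gathered
#' diagnostic factor and differential hypothesis, with an unset label for
#' the student to fill with `I` (increases), `D` (decreases) or `N`
#' (does not affect). A pure query — it does not change or log on the
#' session.
#'
#' @param session A [new_session()] with a non-empty differential and at
#'   least one gathered factor.
#' @return A tibble `(factor, hypothesis, label = NA)`.
#' @export
build_binary_grid <- function(session) {
  stopifnot(inherits(session, "vp_session"))
  if (length(session$differential) == 0) {
    stop("build_binary_grid: the differential is empty; ",
         "propose diagnostic hypotheses first")
  }
  if (length(session$gathered) == 0) {
    stop("build_binary_grid: no diagnostic factors gathered yet")
  }
  tidyr::expand_grid(factor = session$gathered,
                     hypothesis = session$differential) |>
    dplyr::mutate(label = NA_character_)
}

#' Submit a filled binary-analysis grid
#'
#' Every cell is compared with the authored reference grid; mistakes are
#' tallied per hypothesis, wrong cells get inner-loop feedback carrying
#' the correct relationship, and the grading is stored for the learner
#' model and the end-of-case summary.
#'
#' @param session An open [new_session()].
#' @param grid A tibble `(factor, hypothesis, label)` as produced by
#'   [build_binary_grid()], fully filled with `I`/`D`/`N`.
#' @return The updated session; `session$last$grading` is the per-cell
#'   tibble (with `reference_label` and `correct`) and
#'   `session$last$mistakes` the per-hypothesis mistake counts.
#' @export
submit_binary_grid <- function(session, grid) {
  check_open(session)
  grid <- tibble::as_tibble(grid)
  stopifnot(all(c("factor", "hypothesis", "label") %in% names(grid)))
  unset <- is.na(grid$label) | !grid$label %in% c("I", "D", "N")
  if (any(unset)) {
    stop("submit_binary_grid: unfilled or invalid cell(s): ",
         paste(grid$factor[unset], grid$hypothesis[unset],
               sep = "/", collapse = ", "))
  }
  graded <- dplyr::left_join(
    grid, dplyr::rename(session$case$grid, reference_label = "label"),
    by = c("factor", "hypothesis")
  )
  if (any(is.na(graded$reference_label))) {
    bad <- is.na(graded$reference_label)
    stop("submit_binary_grid: cell(s) outside the reference grid: ",
         paste(graded$factor[bad], graded$hypothesis[bad],
               sep = "/", collapse = ", "))
  }
  graded$correct <- graded$label == graded$reference_label
  mistakes <- graded |>
    dplyr::group_by(.data$hypothesis) |>
    dplyr::summarise(cells = dplyr::n(),
                     mistakes = sum(!.data$correct), .groups = "drop")
  wrong <- graded[!graded$correct, , drop = FALSE]
  fb <- if (nrow(wrong)) {
    inner_feedback("grid_mistakes",
                   payload = list(corrections = wrong[, c("factor", "hypothesis",
                                                          "reference_label")]))
  } else {
    inner_feedback("grid_correct")
  }
  session$grid_submissions <- c(session$grid_submissions,
                                list(list(grading = graded, mistakes = mistakes)))
  session$last <- list(action = "submit_binary_grid", grading = graded,
                       mistakes = mistakes, feedback = fb)
  log_action(session, "submit_binary_grid",
             as.character(jsonlite::toJSON(grid, dataframe = "rows")),
             if (nrow(wrong)) "grid_mistakes" else "grid_correct", fb)
}

#' Submit pattern-analysis links
#'
#' In the pattern analysis the student weighs the factor-to-hypothesis
#' relationships established in the binary analysis: a positive link
#' (drawn blue) when the factor increases the hypothesis's probability, a
#' negative link (red) when it decreases it, no link when it has no
#' effect, each with low or high weight (line thickness). Link signs are
#' checked for consistency with the student's own most recent binary
#' grid (`I` <-> positive, `D` <-> negative, `N` <-> none), and each
#' hypothesis receives a display score in `[0, 1]` for rendering its node
#' circumference: the signed weight sum (high = 2, low = 1) rescaled from
#' `[-M, M]` to `[0, 1]`, where `M` is the hypothesis's total absolute
#' weight (0.5 when the hypothesis has no links).
#'
#' @param session An open [new_session()] with at least one submitted
#'   binary grid.
#' @param links A tibble `(factor, hypothesis, sign, weight)` with `sign`
#'   in `positive`/`negative`/`none` and `weight` in `low`/`high`
#'   (`weight` is ignored when `sign` is `none`).
#' @return The updated session; `session$last$inconsistent` lists links
#'   disagreeing with the binary grid and `session$last$scores` the
#'   per-hypothesis display scores.
#' @export
submit_pattern_links <- function(session, links) {
  check_open(session)
  links <- tibble::as_tibble(links)
  stopifnot(all(c("factor", "hypothesis", "sign", "weight") %in% names(links)))
  if (!all(links$sign %in% c("positive", "negative", "none"))) {
    stop("submit_pattern_links: sign must be positive, negative or none")
  }
  if (!all(links$weight %in% c("low", "high") | links$sign == "none")) {
    stop("submit_pattern_links: weight must be low or high")
  }
  bad_f <- setdiff(links$factor, session$gathered)
  if (length(bad_f)) {
    stop("submit_pattern_links: link references ungathered factor(s): ",
         paste(bad_f, collapse = ", "))
  }
  bad_h <- setdiff(links$hypothesis, session$differential)
  if (length(bad_h)) {
    stop("submit_pattern_links: link references hypothesis(es) outside the ",
         "differential: ", paste(bad_h, collapse = ", "))
  }
  if (length(session$grid_submissions) == 0) {
    stop("submit_pattern_links: complete the binary analysis first")
  }
  student_grid <- session$grid_submissions[[length(session$grid_submissions)]]$grading
  expected_sign <- c(I = "positive", D = "negative", N = "none")
  joined <- dplyr::left_join(links, student_grid[, c("factor", "hypothesis", "label")],
                             by = c("factor", "hypothesis"))
  joined$expected <- unname(expected_sign[joined$label])
  inconsistent <- joined[!is.na(joined$expected) & joined$sign != joined$expected,
                         c("factor", "hypothesis", "sign", "expected")]

  w <- ifelse(links$sign == "none", 0,
              ifelse(links$weight == "high", 2, 1)) *
       ifelse(links$sign == "negative", -1, 1)
  scores <- tibble::tibble(hypothesis = session$differential) |>
    dplyr::left_join(
      tibble::tibble(hypothesis = links$hypothesis, w = w) |>
        dplyr::group_by(.data$hypothesis) |>
        dplyr::summarise(s = sum(.data$w), m = sum(abs(.data$w)),
                         .groups = "drop"),
      by = "hypothesis"
    ) |>
    dplyr::mutate(score = dplyr::if_else(is.na(.data$m) | .data$m == 0, 0.5,
                                         (.data$s + .data$m) / (2 * .data$m))) |>
    dplyr::select("hypothesis", "score")

  fb <- if (nrow(inconsistent)) {
    inner_feedback("pattern_inconsistent",
                   payload = list(inconsistent = inconsistent))
  } else {
    inner_feedback("pattern_consistent")
  }
  session$pattern_links <- links
  session$last <- list(action = "submit_pattern_links",
                       inconsistent = inconsistent, scores = scores,
                       feedback = fb)
  log_action(session, "submit_pattern_links",
             as.character(jsonlite::toJSON(links, dataframe = "rows")),
             if (nrow(inconsistent)) "pattern_inconsistent" else "pattern_consistent",
             fb)
}

#' Select the final diagnosis and close the session
#'
#' The chosen hypothesis must already be part of the differential. The
#' outcome is `correct` iff it equals the case's authored final
#' diagnosis; the session is then finished and ready for the outer-loop
#' summary ([outer_summary()]).
#'
#' @param session An open [new_session()].
#' @param hypothesis A hypothesis id from the differential.
#' @return The updated (finished) session; `session$final_outcome` is
#'   `"correct"` or `"incorrect"`.
#' @export
select_final_diagnosis <- function(session, hypothesis) {
  check_open(session)
  if (!hypothesis %in% session$differential) {
    stop("select_final_diagnosis: '", hypothesis,
         "' is not part of the differential diagnosis")
  }
  correct <- hypothesis == session$case$final_diagnosis
  session$finished <- TRUE
  session$final_choice <- hypothesis
  session$final_outcome <- if (correct) "correct" else "incorrect"
  fb <- inner_feedback(if (correct) "final_correct" else "final_incorrect",
                       payload = list(final_diagnosis = session$case$final_diagnosis))
  session$last <- list(action = "select_final_diagnosis",
                       outcome = session$final_outcome, feedback = fb)
  log_action(session, "select_final_diagnosis", hypothesis,
             if (correct) "final_correct" else "final_incorrect", fb)
}

#' Extract the session action log
#'
#' @param session A [new_session()].
#' @return The append-only log tibble: one row per operation invoked,
#'   with timestamp, action, input text, outcome category and feedback.
#' @export
session_log <- function(session) {
  stopifnot(inherits(session, "vp_session"))
  session$log
}

#' Write / read a session log as JSON lines
#'
#' One action per line with fields timestamp, action, input, outcome and
#' feedback codes — the learner-analytics export format.
#'
#' @param session A [new_session()] (for writing).
#' @param path File path.
#' @return `write_session_log` returns `path` invisibly;
#'   `read_session_log` returns the log tibble.
#' @export
write_session_log <- function(session, path) {
  log <- session_log(session)
  lines <- vapply(seq_len(nrow(log)), function(i) {
    jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  dplyr::bind_rows(lapply(lines, function(l) {
    tibble::as_tibble(jsonlite::fromJSON(l))
  }))
}

#' Replay a session log against a fresh session
#'
#' Re-executes every logged action, in order, on a new session built from
#' the same case, ontology and matcher. With identical models the engine
#' is deterministic, so the replayed session reproduces the original
#' final state and feedback stream exactly (timestamps are taken from the
#' log).
#'
#' @param log A log tibble from [session_log()] or [read_session_log()].
#' @param case,ontology,matcher,threshold,min_sim As in [new_session()].
#' @return The replayed `vp_session`.
#' @export
replay_log <- function(log, case, ontology, matcher, threshold = 0.5,
                       min_sim = 0.2) {
  i <- 0L
  clock <- function() {
    log$timestamp[min(i, nrow(log))]
  }
  session <- new_session(case, ontology, matcher, threshold = threshold,
                         min_sim = min_sim, clock = clock)
  # the injected clock reads the original timestamps back, keyed by step
  for (k in seq_len(nrow(log))) {
    i <- k
    input <- log$input[k]
    session <- switch(
      log$action[k],
      review_scenario = review_scenario(session),
      ask_history = ask_history(session, input),
      request_exam_or_test = request_exam_or_test(session, input),
      propose_hypothesis = propose_hypothesis(session, input),
      submit_binary_grid = submit_binary_grid(
        session, jsonlite::fromJSON(input)),
      submit_pattern_links = submit_pattern_links(
        session, jsonlite::fromJSON(input)),
      select_final_diagnosis = select_final_diagnosis(session, input),
      stop("replay_log: unknown action '", log$action[k], "'")
    )
  }
  session
}
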