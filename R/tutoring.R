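# inner-loop feedback catalog: outcome category -> (code, message template).
# The codes are the step-feedback categories evidenced by the simulator's
# behaviour; the catalog is a closed mapping (every engine outcome has
# exactly one code) and can be extended alongside new outcomes.
feedback_catalog <- list(
  scenario_reviewed   = list(code = "correct_action",
                             message = "Scenario reviewed; the presenting findings were added to your gathered factors."),
  question_matched    = list(code = "correct_action",
                             message = "Question understood; the patient's answer is shown."),
  question_unmatched  = list(code = "not_understood",
                             message = "The question was not understood; please rephrase it."),
  exam_matched        = list(code = "correct_action",
                             message = "The requested exam/test is relevant for this case; see its finding."),
  exam_unmatched      = list(code = "inappropriate_exam",
                             message = "An inappropriate exam or test was asked for: it is not part of this case's reference list."),
  hypothesis_correct  = list(code = "correct_action",
                             message = "The diagnostic hypothesis is correct and was added to your differential diagnosis."),
  hypothesis_close_ancestor = list(code = "be_more_specific",
                             message = "Your hypothesis is too general; be more specific."),
  hypothesis_close    = list(code = "close_hypothesis_hint",
                             message = "Your hypothesis is close to a reference hypothesis; reconsider in that direction."),
  hypothesis_incorrect = list(code = "incorrect_hypothesis",
                             message = "The hypothesis does not fit this clinical picture and was not added to the differential."),
  hypothesis_unrecognized = list(code = "not_understood",
                             message = "The hypothesis was not recognized; please rephrase it."),
  grid_correct        = list(code = "correct_action",
                             message = "Binary analysis correct: every relationship matches the reference."),
  grid_mistakes       = list(code = "wrong_binary_cell",
                             message = "Some binary-analysis cells are wrong; the correct relationships are attached."),
  pattern_consistent  = list(code = "correct_action",
                             message = "Pattern links are consistent with your binary analysis."),
  pattern_inconsistent = list(code = "wrong_binary_cell",
                             message = "Some pattern links contradict your own binary analysis; see the attached list."),
  final_correct       = list(code = "correct_action",
                             message = "Correct: you selected the authored final diagnosis."),
  final_incorrect     = list(code = "incorrect_hypothesis",
                             message = "That is not the correct final diagnosis for this case."),
  summary             = list(code = "review_topics",
                             message = "Review the topics where you made the most binary-analysis mistakes.")
)

#' Inner-loop feedback for an engine outcome
#'
#' Deterministically maps an outcome category produced by a session
#' operation to a feedback code from the closed catalog
#' (`inappropriate_exam`, `be_more_specific`, `close_hypothesis_hint`,
#' `not_understood`, `wrong_binary_cell`, `incorrect_hypothesis`,
#' `correct_action`, `review_topics`) with a templated message and an
#' optional structured payload (e.g. the correct cell labels, or the
#' nearest reference hypothesis).
#'
#' @param outcome Outcome category string (e.g. `"exam_unmatched"`).
#' @param payload Optional list of structured details attached to the
#'   feedback.
#' @return A one-row tibble `(code, message)` with the payload in
#'   `attr(, "payload")`.
#' @export
inner_feedback <- function(outcome, payload = NULL) {
  entry <- feedback_catalog[[outcome]]
  if (is.null(entry)) {
    stop("inner_feedback: unknown outcome category '", outcome,
         "' (the feedback catalog must cover every engine outcome)")
  }
  out <- tibble::tibble(code = entry$code, message = entry$message)
  attr(out, "payload") <- payload
  out
}

#' Feedback codes of the inner-loop catalog
#'
#' @return Character vector of the closed catalog codes.
#' @export
feedback_codes <- function() {
  sort(unique(vapply(feedback_catalog, `[[`, character(1), "code")))
}

#' Outer-loop end-of-simulation summary
#'
#' Summarizes, per diagnostic hypothesis, how many mistakes the student
#' made in the (most recent) binary analysis, sorted by descending
#' mistake count (ties by smallest hypothesis id), each paired with the
#' case's configured review-topic link — the "review that specific
#' topic" recommendation.
#'
#' @param session A finished session.
#' @return A tibble `(hypothesis, mistakes, cells, review_link)`. When no
#'   binary grid was submitted, an empty tibble with a `notice`
#'   attribute.
#' @export
outer_summary <- function(session) {
  stopifnot(inherits(session, "vp_session"))
  if (!session$finished) {
    stop("outer_summary: the session is not finished yet")
  }
  empty <- tibble::tibble(hypothesis = character(0), mistakes = integer(0),
                          cells = integer(0), review_link = character(0))
  if (length(session$grid_submissions) == 0) {
    attr(empty, "notice") <- "no binary analysis was submitted in this session"
    return(empty)
  }
  mk <- session$grid_submissions[[length(session$grid_submissions)]]$mistakes
  links <- session$case$review_links
  out <- mk |>
    dplyr::mutate(review_link = dplyr::coalesce(
      unname(links[.data$hypothesis]), NA_character_)) |>
    dplyr::arrange(dplyr::desc(.data$mistakes), .data$hypothesis) |>
    dplyr::select("hypothesis", "mistakes", "cells", "review_link")
  out
}

#' Discretize binary-analysis performance into a BKT observation
#'
#' Aggregates a student's per-hypothesis binary-analysis grading into the
#' binary observation the learner model consumes: the hypothesis counts
#' as answered correctly when the fraction of correct cells,
#' `1 - mistakes/cells`, reaches `success_fraction`.
#'
#' @param mistakes Integer vector of mistake counts per hypothesis.
#' @param cells Integer vector (same length) of cell counts, all >= 1.
#' @param success_fraction Threshold in `[0, 1]` (default 0.8).
#' @return Logical vector: `TRUE` = correct observation.
#' @export
binary_observation <- function(mistakes, cells, success_fraction = 0.8) {
  if (any(cells < 1)) stop("binary_observation: cells per hypothesis must be >= 1")
  if (any(mistakes < 0 | mistakes > cells)) {
    stop("binary_observation: mistakes must lie in [0, cells]")
  }
  (1 - mistakes / cells) >= success_fraction
}

#' Create a learner state
#'
#' Per-skill Bayesian Knowledge Tracing state for one student: each skill
#' (a diagnostic-hypothesis concept) carries its observation history and
#' its current mastery posterior, updated by [update_learner()] after
#' every simulation.
#'
#' @param params A [bkt_params()] shared by the skills.
#' @return An object of class `learner_state`.
#' @export
learner_state <- function(params) {
  stopifnot(inherits(params, "bkt_params"))
  structure(list(params = params,
                 skills = tibble::tibble(skill = character(0),
                                         posterior = numeric(0),
                                         history = list())),
            class = "learner_state")
}

#' @export
print.learner_state <- function(x, ...) {
  cat(sprintf("<learner_state> %d skill(s)\n", nrow(x$skills)))
  if (nrow(x$skills)) print(mastery_report(x))
  invisible(x)
}

#' Update a learner state with one observation
#'
#' Applies [bkt_update()] to the skill's mastery posterior (new skills
#' start at the prior `p_L0`) and appends to its history.
#'
#' @param state A [learner_state()].
#' @param skill Skill (hypothesis concept) id.
#' @param correct Logical observation.
#' @return The updated `learner_state`.
#' @export
update_learner <- function(state, skill, correct) {
  stopifnot(inherits(state, "learner_state"))
  i <- match(skill, state$skills$skill)
  if (is.na(i)) {
    state$skills <- dplyr::bind_rows(
      state$skills,
      tibble::tibble(skill = skill, posterior = state$params$p_L0,
                     history = list(integer(0))))
    i <- nrow(state$skills)
  }
  state$skills$posterior[i] <- bkt_update(state$params,
                                          state$skills$posterior[i], correct)
  state$skills$history[[i]] <- c(state$skills$history[[i]],
                                 as.integer(correct))
  state
}

#' Fold a finished session into the learner state
#'
#' Converts the session's most recent binary-analysis grading into one
#' binary observation per diagnostic hypothesis
#' ([binary_observation()]) and updates the corresponding skills.
#'
#' @param state A [learner_state()].
#' @param session A session with at least one submitted binary grid.
#' @param success_fraction Threshold passed to [binary_observation()].
#' @return The updated `learner_state`.
#' @export
record_session <- function(state, session, success_fraction = 0.8) {
  stopifnot(inherits(session, "vp_session"))
  if (length(session$grid_submissions) == 0) {
    stop("record_session: the session has no submitted binary grid")
  }
  mk <- session$grid_submissions[[length(session$grid_submissions)]]$mistakes
  obs <- binary_observation(mk$mistakes, mk$cells, success_fraction)
  for (j in seq_len(nrow(mk))) {
    state <- update_learner(state, mk$hypothesis[j], obs[j])
  }
  state
}

#' Per-skill mastery report
#'
#' @param state A [learner_state()] with at least one skill.
#' @param mastery_threshold Posterior above which a skill counts as
#'   mastered (default 0.95).
#' @return A tibble `(skill, posterior, n_observations, status)` sorted
#'   by ascending posterior (weakest skills first).
#' @export
mastery_report <- function(state, mastery_threshold = 0.95) {
  stopifnot(inherits(state, "learner_state"))
  if (nrow(state$skills) == 0) {
    stop("mastery_report: the learner state has no skills yet")
  }
  state$skills |>
    dplyr::mutate(n_observations = lengths(.data$history),
                  status = dplyr::if_else(.data$posterior >= mastery_threshold,
                                          "mastered", "developing")) |>
    dplyr::arrange(.data$posterior) |>
    dplyr::select("skill", "posterior", "n_observations", "status")
}

#' Persist / restore a learner state as JSON
#'
#' One JSON document per student: BKT parameters plus, per skill, the
#' observation history and current posterior. Histories are append-only;
#' re-reading and re-applying the stored history reproduces the
#' posterior.
#'
#' @param state A [learner_state()].
#' @param path File path.
#' @return `write_learner_state` returns `path` invisibly;
#'   `read_learner_state` returns the state.
#' @export
write_learner_state <- function(state, path) {
  stopifnot(inherits(state, "learner_state"))
  obj <- list(
    params = state$params[c("p_L0", "p_T", "p_S", "p_G")],
    skills = lapply(seq_len(nrow(state$skills)), function(i) {
      list(skill = state$skills$skill[i],
           posterior = state$skills$posterior[i],
           history = state$skills$history[[i]])
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_learner_state
#' @export
read_learner_state <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  state <- learner_state(bkt_params(obj$params$p_L0, obj$params$p_T,
                                    obj$params$p_S, obj$params$p_G))
  for (sk in obj$skills) {
    state$skills <- dplyr::bind_rows(
      state$skills,
      tibble::tibble(skill = sk$skill, posterior = as.numeric(sk$posterior),
                     history = list(as.integer(unlist(sk$history)))))
  }
  state
}
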