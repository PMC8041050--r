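# case loading ---------------------------------------------------------------

test_that("the worked example case validates and round-trips through JSON", {
  case <- table1_case()
  expect_length(case$hypotheses, 2)
  expect_equal(nrow(case$grid), 6)
  g <- function(f, h) case$grid$label[case$grid$factor == f &
                                      case$grid$hypothesis == h]
  expect_equal(g("f_temp", "pharyngitis"), "I")
  expect_equal(g("f_temp", "pneumonia"), "I")
  expect_equal(g("f_pharynx", "pharyngitis"), "D")
  expect_equal(g("f_pharynx", "pneumonia"), "N")
  expect_equal(g("f_xray", "pharyngitis"), "N")
  expect_equal(g("f_xray", "pneumonia"), "I")
  expect_equal(case$final_diagnosis, "pneumonia")

  p <- tempfile(fileext = ".json")
  write_case(case, p)
  case2 <- load_case(p)
  expect_equal(case2$grid, case$grid)
  expect_equal(case2$questions$factors, case$questions$factors)
  expect_equal(case2$review_links, case$review_links)

  shipped <- load_case(system.file("extdata", "table1_case.json",
                                   package = "vptutor"))
  expect_equal(shipped$grid, case$grid)
})

test_that("case validation names the offending field", {
  case <- table1_case()
  broken <- case
  broken$grid <- case$grid[-1, ]   # one missing cell
  expect_error(do.call(clinical_case, unclass(broken)), "grid.*missing cell")
  broken2 <- case
  broken2$final_diagnosis <- "asthma"
  expect_error(do.call(clinical_case, unclass(broken2)), "final_diagnosis")
  p <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(scenario = "x"), auto_unbox = TRUE), p)
  expect_error(load_case(p), "missing top-level field")
})

# engine flow ----------------------------------------------------------------

fresh_session <- function(case = table1_case()) {
  new_session(case, toy_clinical_ontology(), table1_matcher(case),
              threshold = 0.99, clock = counter_clock())
}

test_that("data gathering reveals factors and logs every action", {
  s <- fresh_session()
  s <- review_scenario(s)
  expect_equal(s$last$scenario, s$case$scenario)

  s <- ask_history(s, "Do you have a fever?")   # verbatim reference
  expect_equal(s$last$matches$reference_question_id, "q_fever")
  expect_match(s$last$matches$answer, "38.5")
  expect_true("f_temp" %in% s$gathered)

  before <- s$gathered
  s <- ask_history(s, "Do you have a fever?")   # idempotent on factors
  expect_identical(s$gathered, before)

  s <- ask_history(s, "wombat xylophone quantum")
  expect_equal(nrow(s$last$matches), 0)
  expect_equal(s$last$feedback$code, "not_understood")

  s <- request_exam_or_test(s, "chest x ray")
  expect_equal(s$last$finding, "Lobar consolidation")
  expect_true("f_xray" %in% s$gathered)
  s <- request_exam_or_test(s, "inspect the pharynx")
  expect_equal(s$last$finding, "No pharyngeal erythema")
  s <- request_exam_or_test(s, "colonoscopy")
  expect_equal(s$last$feedback$code, "inappropriate_exam")
  expect_error(request_exam_or_test(s, "  "), "empty")

  expect_equal(nrow(s$log), 7)
  expect_equal(s$log$step, 1:7)
  expect_equal(s$log$timestamp, sprintf("t%04d", 1:7))
})

test_that("hypothesis proposal feeds the differential with graded feedback", {
  s <- fresh_session()
  s <- propose_hypothesis(s, "pneumonia")
  expect_equal(s$last$match$verdict, "correct")
  expect_equal(s$differential, "pneumonia")
  s <- propose_hypothesis(s, "bronchitis")       # distance 2 from pneumonia
  expect_equal(s$last$match$verdict, "close")
  expect_equal(s$last$feedback$code, "close_hypothesis_hint")
  expect_equal(s$differential, "pneumonia")      # close never enters
  s <- propose_hypothesis(s, "gastroenteritis")  # disconnected
  expect_equal(s$last$match$verdict, "incorrect")
  expect_equal(s$last$feedback$code, "incorrect_hypothesis")
  s <- propose_hypothesis(s, "blorple frobnicates")
  expect_equal(s$last$feedback$code, "not_understood")
  s <- propose_hypothesis(s, "sore throat inflammation")
  expect_equal(s$differential, c("pneumonia", "pharyngitis"))
})

test_that("a too-general hypothesis gets be-more-specific feedback", {
  case <- table1_case()
  case$hypotheses <- c("pharyngitis", "interstitial_pneumonia")
  case$final_diagnosis <- "interstitial_pneumonia"
  case$grid$hypothesis[case$grid$hypothesis == "pneumonia"] <-
    "interstitial_pneumonia"
  case <- do.call(clinical_case, unclass(case)[names(unclass(case)) !=
                                               "review_links"])
  s <- fresh_session(case)
  s <- propose_hypothesis(s, "pneumonia")  # parent of the reference
  expect_equal(s$last$match$verdict, "close")
  expect_equal(s$last$match$distance, 1)
  expect_equal(s$last$feedback$code, "be_more_specific")
})

full_run <- function(grid_edit = identity) {
  s <- fresh_session()
  s <- ask_history(s, "Do you have a fever?")
  s <- request_exam_or_test(s, "inspect the pharynx")
  s <- request_exam_or_test(s, "chest x ray")
  s <- propose_hypothesis(s, "pharyngitis")
  s <- propose_hypothesis(s, "pneumonia")
  grid <- build_binary_grid(s)
  ref <- s$case$grid
  grid$label <- ref$label[match(paste(grid$factor, grid$hypothesis),
                                paste(ref$factor, ref$hypothesis))]
  grid <- grid_edit(grid)
  s <- submit_binary_grid(s, grid)
  s
}

test_that("the binary analysis grades cells against the reference grid", {
  s <- fresh_session()
  expect_error(build_binary_grid(s), "propose diagnostic hypotheses")
  s <- propose_hypothesis(s, "pneumonia")
  expect_error(build_binary_grid(s), "no diagnostic factors")

  s <- full_run()
  expect_equal(nrow(s$grid_submissions[[1]]$grading), 6)
  expect_equal(sum(s$grid_submissions[[1]]$mistakes$mistakes), 0)
  expect_equal(s$last$feedback$code, "correct_action")

  # flip one pneumonia cell
  s2 <- full_run(function(g) {
    i <- which(g$factor == "f_xray" & g$hypothesis == "pneumonia")
    g$label[i] <- "D"
    g
  })
  mk <- s2$grid_submissions[[1]]$mistakes
  expect_equal(mk$mistakes[mk$hypothesis == "pneumonia"], 1)
  expect_equal(mk$mistakes[mk$hypothesis == "pharyngitis"], 0)
  expect_equal(s2$last$feedback$code, "wrong_binary_cell")
  pl <- attr(s2$last$feedback, "payload")$corrections
  expect_equal(pl$reference_label, "I")

  # flipping every cell to a wrong label gives 3 mistakes per hypothesis
  s3 <- full_run(function(g) {
    g$label <- c(I = "D", D = "N", N = "I")[g$label]
    g
  })
  expect_equal(sort(s3$grid_submissions[[1]]$mistakes$mistakes), c(3, 3))

  expect_error(full_run(function(g) { g$label[2] <- NA; g }), "unfilled")
})

test_that("pattern links are checked against the student's own grid and scored", {
  s <- full_run()
  links <- tibble::tibble(
    factor = c("f_xray", "f_pharynx"),
    hypothesis = c("pneumonia", "pharyngitis"),
    sign = c("positive", "negative"),
    weight = c("high", "low"))
  s <- submit_pattern_links(s, links)
  expect_equal(nrow(s$last$inconsistent), 0)
  sc <- s$last$scores
  expect_equal(sc$score[sc$hypothesis == "pneumonia"], 1)   # (+2+2)/4
  expect_equal(sc$score[sc$hypothesis == "pharyngitis"], 0) # (-1+1)/2
  expect_gt(sc$score[sc$hypothesis == "pneumonia"],
            sc$score[sc$hypothesis == "pharyngitis"])

  bad <- dplyr::mutate(links, sign = c("negative", "negative"))
  s2 <- submit_pattern_links(s, bad)
  expect_equal(nrow(s2$last$inconsistent), 1)   # x-ray/pneumonia is I
  expect_equal(s2$last$inconsistent$expected, "positive")

  expect_error(
    submit_pattern_links(s, dplyr::mutate(links, factor = c("f_xray", "ghost"))),
    "ungathered")
})

test_that("final diagnosis closes the session with the equality outcome", {
  s <- full_run()
  expect_error(select_final_diagnosis(s, "asthma"), "not part of the differential")
  s_wrong <- select_final_diagnosis(s, "pharyngitis")
  expect_equal(s_wrong$final_outcome, "incorrect")
  s <- select_final_diagnosis(s, "pneumonia")
  expect_equal(s$final_outcome, "correct")
  expect_true(s$finished)
  expect_error(ask_history(s, "anything?"), "finished")
  expect_error(select_final_diagnosis(s, "pneumonia"), "finished")
})

test_that("gathering stays available after analysis, and state only grows", {
  s <- fresh_session()
  s <- ask_history(s, "Do you have a fever?")
  s <- propose_hypothesis(s, "pneumonia")
  g <- dplyr::mutate(build_binary_grid(s), label = "I")
  s <- submit_binary_grid(s, g)
  # navigation freedom: data gathering after data analysis
  s <- request_exam_or_test(s, "chest x ray")
  expect_true("f_xray" %in% s$gathered)
  expect_equal(nrow(s$log), 4)

  # monotone growth of gathered and differential across the whole log
  sizes <- integer(0); s2 <- fresh_session()
  steps <- list(
    function(x) ask_history(x, "Do you have a fever?"),
    function(x) propose_hypothesis(x, "pneumonia"),
    function(x) request_exam_or_test(x, "colonoscopy"),
    function(x) propose_hypothesis(x, "gastroenteritis"),
    function(x) request_exam_or_test(x, "inspect the pharynx"))
  for (f in steps) {
    prev_g <- s2$gathered; prev_d <- s2$differential
    s2 <- f(s2)
    expect_true(all(prev_g %in% s2$gathered))
    expect_true(all(prev_d %in% s2$differential))
  }
})

test_that("replaying a session log reproduces state and feedback exactly", {
  s <- full_run(function(g) { g$label[1] <- "D"; g })
  links <- tibble::tibble(factor = "f_xray", hypothesis = "pneumonia",
                          sign = "positive", weight = "high")
  s <- submit_pattern_links(s, links)
  s <- select_final_diagnosis(s, "pneumonia")

  lg <- tempfile(fileext = ".jsonl")
  write_session_log(s, lg)
  log2 <- read_session_log(lg)
  expect_equal(nrow(log2), nrow(s$log))

  r <- replay_log(log2, s$case, s$ontology, s$matcher, threshold = 0.99)
  expect_equal(r$log, s$log)             # identical feedback stream
  expect_identical(r$gathered, s$gathered)
  expect_identical(r$differential, s$differential)
  expect_identical(r$final_choice, s$final_choice)
  expect_identical(r$final_outcome, s$final_outcome)
  expect_equal(r$grid_submissions[[1]]$grading, s$grid_submissions[[1]]$grading)
  expect_equal(r$last$feedback, s$last$feedback)
})
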