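Package: vptutor
Title: Virtual Patient Simulation and Intelligent Tutoring for Clinical
    Diagnostic Reasoning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A natural-language virtual patient simulator and intelligent
    tutoring engine for training clinical diagnostic reasoning. Free-text
    diagnostic hypotheses are normalized against a concept ontology by
    Jaccard token matching and graded by graph path distance
    (correct / close / incorrect bands); free-text history-taking questions
    are matched to authored reference questions by a Siamese recurrent
    (LSTM) encoder with Manhattan-distance similarity and a thresholded
    top-3 ranker; a clinical-case engine drives data gathering (anamnesis,
    physical exam, test requests), binary increase/decrease/no-effect
    analysis, pattern analysis and final-diagnosis selection with full
    action logging; a tutoring layer supplies step-by-step inner-loop
    feedback, an end-of-case mistake summary with review links, and a
    Bayesian Knowledge Tracing learner model (two-state hidden Markov
    model) fitted by expectation-maximization. Includes seeded synthetic
    generators (toy ontology, worked clinical case, paraphrase benchmark,
    simulated learners) so the whole pipeline runs without licensed data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
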