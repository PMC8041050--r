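# vptutor

Virtual patient simulation and intelligent tutoring for clinical
diagnostic reasoning, in R.

`vptutor` is for medical-education researchers and simulation authors
who want a scriptable engine — not a UI — for natural-language clinical
case simulation. A student-facing front end (or a test harness) drives
it through four capabilities:

1. **Free-text diagnostic hypothesis grading.** Input text is linked to
   an ontology concept by Jaccard token similarity over labels and
   synonyms, then graded by the is-a graph path distance *d* to the
   case's reference hypotheses: *d* = 0 correct, 1 ≤ *d* ≤ 4 close
   (with a hint toward the nearest reference, or "be more specific"
   when the guess is an ancestor of it), *d* ≥ 5 incorrect.
2. **Free-text history taking.** A Siamese LSTM encoder (one shared
   weight set, hand-written BPTT) scores question pairs with the
   Manhattan similarity `exp(-||h1 - h2||_1)`; a ranker returns the
   reference questions above a probability threshold, at most three.
3. **A clinical-case engine**: scenario review, anamnesis, exams/tests,
   differential building, the I/D/N binary-analysis grid, pattern
   analysis, final diagnosis — with free navigation, exact grading
   against the authored reference, and a replayable action log.
4. **Tutoring**: per-step feedback from a closed catalog, an
   end-of-case mistake summary with review links, and a Bayesian
   Knowledge Tracing learner model (two-state HMM with prior `p_L0`,
   learning `p_T`, slip `p_S`, guess `p_G`; forward algorithm + EM
   fitting with seeded restarts).

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects
have `tidy()`, `glance()` and `autoplot()` methods. Seeded synthetic
generators (toy ontology, a worked case, a paraphrase benchmark,
simulated learners) make the whole pipeline runnable without licensed
data.

## A worked simulation

The shipped example case is the classic pharyngitis-vs-pneumonia
teaching grid: three findings (body temperature 38.5 °C, pharynx
inspection without erythema, chest x-ray with lobar consolidation), two
hypotheses, pneumonia as the authored final diagnosis.

```r
library(vptutor)

case <- table1_case()
ont  <- toy_clinical_ontology()
emb  <- train_embeddings(c(case$questions$text, "do you have pyrexia"),
                         synonym_pairs = data.frame(a = "fever", b = "pyrexia"),
                         dimension = 8, seed = 1)
matcher <- siamese_matcher(emb, hidden_size = 16, seed = 1)

s <- new_session(case, ont, matcher, threshold = 0.99) |>
  ask_history("Do you have a fever?") |>
  request_exam_or_test("chest x ray") |>
  propose_hypothesis("sore throat inflammation") |>
  propose_hypothesis("pneumonia")

s$last$feedback$message
#> [1] "The diagnostic hypothesis is correct and was added to your differential diagnosis."

grid <- build_binary_grid(s)          # 2 factors x 2 hypotheses, unset
grid$label <- c("I", "I", "I", "I")   # student: "everything increases everything"
s <- submit_binary_grid(s, grid) |>
  select_final_diagnosis("pneumonia")

outer_summary(s)
#> # A tibble: 2 × 4
#>   hypothesis  mistakes cells review_link
#>   <chr>          <int> <int> <chr>
#> 1 pharyngitis        1     2 https://example.org/topics/pharyngitis
#> 2 pneumonia          0     2 https://example.org/topics/pneumonia
```

The student mis-labelled one pharyngitis cell (a chest x-ray
consolidation does not bear on pharyngitis), so the outer loop puts
pharyngitis on top with one mistake and its review link. Folding the
session into a learner state updates the per-disease mastery
posteriors:

```r
st <- learner_state(bkt_params(p_L0 = 0.3, p_T = 0.2, p_S = 0.1, p_G = 0.2)) |>
  record_session(s)
mastery_report(st)
#> # A tibble: 2 × 4
#>   skill       posterior n_observations status
#>   <chr>           <dbl>          <int> <chr>
#> 1 pharyngitis     0.241              1 developing
#> 2 pneumonia       0.727              1 developing
```

## Package tour

| area | functions |
|---|---|
| ontology | `ontology()`, `read_ontology()`, `match_concept()`, `path_distance()`, `is_ancestor()`, `classify_hypothesis()` |
| question matching | `train_embeddings()`, `siamese_matcher()`, `train_matcher()`, `pair_similarity()`, `rank_questions()`, `evaluate_rank_accuracy()`, `save_matcher()` |
| simulation | `clinical_case()`, `load_case()`, `new_session()`, `ask_history()`, `request_exam_or_test()`, `propose_hypothesis()`, `build_binary_grid()`, `submit_binary_grid()`, `submit_pattern_links()`, `select_final_diagnosis()`, `replay_log()` |
| tutoring | `inner_feedback()`, `outer_summary()`, `binary_observation()`, `bkt_params()`, `bkt_update()`, `bkt_sequence_likelihood()`, `bkt_fit()`, `learner_state()`, `record_session()`, `mastery_report()` |
| synthetic data | `make_toy_ontology()`, `toy_clinical_ontology()`, `table1_case()`, `make_paraphrase_benchmark()`, `simulate_learners()` |

The methods vignette (`vignettes/vptutor-methods.Rmd`) documents the
models, defaults and design decisions in detail.
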