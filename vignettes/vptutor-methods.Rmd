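---
title: "Methods: natural-language virtual patient simulation and tutoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: natural-language virtual patient simulation and tutoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

vptutor implements the computational core of a natural-language virtual
patient simulator with an intelligent tutoring layer. A student works
through an authored clinical case: they question the virtual patient,
request physical exams and medical tests, propose diagnostic hypotheses
in free text, fill in a binary (increase/decrease/no-effect) analysis of
how each gathered finding bears on each hypothesis, weigh those
relationships in a pattern analysis, and commit to a final diagnosis.
The tutoring layer grades each step against the case author's reference
content, gives immediate feedback, summarizes weaknesses at the end of
the case, and tracks each student's per-disease skill across simulations
with a Bayesian Knowledge Tracing model. This vignette describes the
models, the parameters that matter, and the design decisions taken where
the design was genuinely open.

## Grading free-text diagnostic hypotheses

A hypothesis typed by the student ("lung inflammation") is first linked
to a concept of a clinical ontology. Each concept carries a preferred
label and synonyms; the link is chosen by maximal Jaccard similarity
$|A \cap B| / |A \cup B|$ between stop-word-free token sets of the input
and of each concept text. Ties go to the lexicographically smallest
concept id so that matching is deterministic and testable. Below a
minimum similarity (default `min_sim = 0.2`; no published floor exists,
and 0.2 tolerates partial-phrase matches while rejecting noise) the
input is *unrecognized* and the student is asked to rephrase.

The linked concept is then compared with the case's reference hypotheses
by **graph path distance**: the minimum number of edges of any path
connecting the two concepts in the is-a graph, treated as undirected
(a child and its parent are one edge apart in either direction).
Verdicts follow the published banding:

| distance | verdict |
|---|---|
| 0 | correct — joins the differential |
| 1–4 | close — the student is pointed toward the nearest reference |
| ≥ 5 or disconnected | incorrect |

The source banding leaves distance exactly 5 unassigned ("between 1 and
4" is close, "greater than 5" is incorrect); we classify 5 as incorrect,
keeping the close band exactly as printed. A close hypothesis that is an
*ancestor* of the nearest reference (pneumonia vs interstitial
pneumonia) is a special case: the student is told to be more specific
rather than merely "close". Only is-a edges are used; no other
relationship types and no semantic similarity beyond edge counting.

The package ships no licensed terminology. `toy_clinical_ontology()`
provides a small hand-authored respiratory hierarchy for the worked
example, `make_toy_ontology()` generates seeded synthetic trees, and
`read_ontology()` loads any concept/edge table in the same shape, so a
licensed release can be plugged in by the user.

## Matching anamnestic questions

History-taking questions cannot be matched by token overlap alone — the
meaning of a sentence depends on its syntax — so question matching uses
a **Siamese recurrent (LSTM) encoder**. Both questions pass through one
shared-parameter encoder (weight sharing is structural: there is only
one set of weights); each question's final hidden state is taken, and
the pair is scored with the Manhattan-distance similarity

$$s(q_1, q_2) = \exp\big(-\lVert h_1 - h_2 \rVert_1\big) \in (0, 1],$$

which is symmetric and equals 1 exactly when the hidden states
coincide. Words enter through a word-embedding table trained by
`train_embeddings()`: a seeded skip-gram objective with negative
sampling, augmented with a dictionary-supervision term that pulls
declared synonym pairs together (medical synonym pairs are exactly what
pure distributional training gets wrong on small corpora). Output
vectors are unit-normalized so the encoder's gates see a consistent
input scale. Out-of-vocabulary words map to a dedicated zero-initialized
UNK vector that trains with the encoder; the embedding is behind an
interface (`embedding_model()`) so pretrained vectors can be plugged in.

Training (`train_matcher()`) minimizes the squared error between the
pair similarity and the binary equivalence label by backpropagation
through time with Adam updates, one pair per step. Defaults: hidden size
50, embedding dimension 16, maximum question length 30 tokens
(truncation keeps the first tokens), learning rate 0.02, 80 epochs.
Small-corpus recurrent training is sensitive to initialization and its
iterates are noisy, so three standard stabilizers are built in: the
optimizer runs from 5 seeded restarts; each restart also produces a tail
average of its final quarter of epochs (Polyak-style iterate averaging);
and every candidate is scored on a 15% slice of the labeled pairs held
back from training. The score is retrieval-style rather than a pair
loss: each held-back equivalent pair contributes a query (its
paraphrase) that must rank its own anchor question first among the
slice's anchors, which mirrors what the downstream question ranker
consumes — pairwise losses (squared error, AUC) proved too weakly
coupled to retrieval quality to select on. The best candidate across
restarts is returned. Model selection consumes only training pairs —
evaluation data are never touched. Everything is deterministic given the
seed, and the analytic gradient is verified against finite differences
in the test suite.

At simulation time the **question ranker** (`rank_questions()`) scores
the student's question against every reference question, sorts
descending (ties to the smallest reference id) and returns those above a
probability threshold (default 0.5, configurable) — *up to a maximum of
three*. Returning more would hand the student reference questions they
had not conceived; returning none is a valid outcome that triggers a
rephrase prompt. Accuracy evaluation (`evaluate_rank_accuracy()`) uses
pure ranking without the threshold: rank-k accuracy is the fraction of
test questions whose true reference appears in the top k.

## The simulation engine

A session (`new_session()`) is a functional state machine over a
validated case definition (`clinical_case()`, JSON schema in
`load_case()`): gathered factors, differential, submitted grids, and an
append-only action log. Operations take the session first and return
the updated session, so they chain with the pipe. The student can move
freely between data gathering and data analysis until the final
diagnosis closes the session; gathered factors and the differential only
grow. Exam and test requests are matched by the Jaccard concept matcher
rather than the Siamese network: exam names are short noun phrases where
token overlap suffices, and no published mechanism dictates otherwise.

The binary analysis grid spans the *student-gathered* factors times the
differential (the table lists what was "identified thus far", not the
full reference content). Grading is exact cell-by-cell comparison
against the reference grid. The pattern analysis checks the student's
link signs against their own binary grid (I–positive, D–negative,
N–none) and computes a display score per hypothesis for rendering: the
signed weight sum (high = 2, low = 1) rescaled from $[-M, M]$ to
$[0, 1]$, where $M$ is the hypothesis's total absolute weight (0.5 when
it has no links). The rescaling formula is our choice — only the
visualization semantics are prescribed.

Timestamps come from an injectable clock, so `replay_log()` can re-run a
logged session against fresh models and reproduce the identical final
state and feedback stream — the engine is deterministic given its
models. Matched reference questions stay matchable on repeat (answers
can be re-read; factor gathering is idempotent).

## Tutoring: feedback, summary, learner model

Inner-loop feedback is a closed deterministic mapping from engine
outcome categories to a feedback catalog (`inappropriate_exam`,
`be_more_specific`, `close_hypothesis_hint`, `not_understood`,
`wrong_binary_cell`, `incorrect_hypothesis`, `correct_action`,
`review_topics`), each with a templated message and structured payload
(e.g. the correct cell labels). `incorrect_hypothesis` completes the
catalog for rejected hypotheses, which need feedback distinct from
"not understood". The outer loop (`outer_summary()`) sorts hypotheses by
binary-analysis mistakes (most recent submission; re-submissions
supersede) and attaches per-hypothesis review links from the case file —
a configurable topic→URL map rather than any commercial service.

The learner model is **Bayesian Knowledge Tracing**: a two-state hidden
Markov model per skill (skill = diagnostic hypothesis), with prior
mastery $p_{L0}$, learning rate $p_T$, slip $p_S$ and guess $p_G$, and
no forgetting (known→unknown fixed at 0, as in the standard
formulation). Binary-analysis performance is discretized into the
per-hypothesis observation by a success fraction: correct iff at least
80% of that hypothesis's cells were right (the aggregation is not
prescribed; 0.8 maps "at most one slip in a typical 3–6 cell column" to
success). Updates use the closed-form Bayes step followed by the
learning step; sequence likelihoods use the scaled forward algorithm,
which the tests verify against brute-force enumeration over all $2^T$
hidden paths. `bkt_fit()` runs Baum–Welch from 5 seeded restarts,
keeping the best final likelihood; fits violating the identifiability
guard $p_S + p_G < 1$ are canonicalized by relabeling the states. Fits
are per-skill and global across students. Mastery is reported at a 0.95
posterior threshold (configurable), weakest skills first.

## Synthetic data and what it does (not) show

No training pairs, test sets or licensed ontology from the original
system are available, so the package generates its own study materials:

* `table1_case()` — the worked pharyngitis/pneumonia case with the
  published 3×2 reference grid and pneumonia as final diagnosis.
* `make_paraphrase_benchmark()` — the question-matching benchmark at
  desk scale: 6 simulations with 16 reference symptom questions each,
  600 balanced training pairs, and 18 held-out test questions per
  simulation (108 total, mirroring the published protocol's 6 test sets
  at roughly one fifth of its 547 questions). Paraphrases are produced
  by slot substitution — question frame × symptom synonym — with no
  neural augmentation, so the benchmark is deterministic and
  inspectable. Half of the equivalent training pairs anchor on the
  canonical reference phrasing, since that is what the deployed ranker
  compares against; inequivalent pairs cross symptoms, with a 10%
  admixture of off-topic distractors. Test questions use
  frame × synonym combinations never seen in training.
* `simulate_learners()` — binary observation sequences drawn from the
  BKT generating process, used for parameter-recovery testing (500
  learners × 20 opportunities recovers all four parameters within 0.05).

The benchmark's linguistic variety is far below real student questions:
slot substitution produces clean, short, grammatical paraphrases with a
closed vocabulary. Passing the rank-accuracy bars here shows the
pipeline learns and generalizes across held-out paraphrase forms; it
does not certify performance on free-form clinical language. Likewise
the toy ontology exercises the distance bands, not the coverage of a
full terminology.

## Numerical choices and limitations

* Problem sizes were chosen for desk-scale runs: benchmark training
  takes a few minutes on one CPU; BKT fitting with 500×20 observations
  and 5 restarts takes seconds.
* All ties break deterministically (smallest id); all stochastic
  procedures are seeded; generators are bit-reproducible.
* EM stops when the log-likelihood gain drops below 1e-6 or after 200
  iterations; parameters are clipped to [1e-6, 1−1e-6] to keep
  emissions proper.
* Degenerate inputs error early with named fields: empty reference
  lists, unfilled grid cells, unknown concept ids, single-class training
  sets, non-identifiable (all-identical) observation histories.
* The Siamese similarity equals 1 only for identical hidden states, so
  label-1 pairs are never fit exactly; training targets separation, not
  calibration. Ranking uses relative scores, so this does not affect
  matching.
* Not implemented by design: UI layers, multi-user services, multimedia
  attachments, therapy/management modules, Transformer-style matchers,
  and relationship types beyond is-a.
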