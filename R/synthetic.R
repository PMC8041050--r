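#' Generate a toy disease ontology
#'
#' A rooted is-a tree of synthetic disease concepts — a stand-in for a
#' licensed clinical terminology — with generated labels and 1--3
#' synonyms per concept. Node count is the geometric series
#' `(branching^(depth+1) - 1) / (branching - 1)`. Deterministic given the
#' seed.
#'
#' @param depth Tree depth (>= 2; the root is depth 0).
#' @param branching Children per node (>= 2).
#' @param seed Integer seed.
#' @return An [ontology()].
#' @export
make_toy_ontology <- function(depth = 3, branching = 2, seed = 1L) {
  if (depth < 2 || branching < 2) {
    stop("make_toy_ontology: need depth >= 2 and branching >= 2")
  }
  withr::local_seed(seed)
  syll <- c("car", "dio", "neph", "hepa", "pulmo", "derma", "neuro", "gastro",
            "myo", "osteo", "itis", "osis", "pathy", "algia", "emia")
  ids <- "d1"; labels <- "disease"; parents <- NA_character_
  level <- "d1"; counter <- 1L
  for (dd in seq_len(depth)) {
    nxt <- character(0)
    for (p in level) {
      for (b in seq_len(branching)) {
        counter <- counter + 1L
        id <- sprintf("d%d", counter)
        lab <- paste0(paste(sample(syll, 2), collapse = ""), " disorder ",
                      counter)
        ids <- c(ids, id); labels <- c(labels, lab); parents <- c(parents, p)
        nxt <- c(nxt, id)
      }
    }
    level <- nxt
  }
  synonyms <- lapply(seq_along(ids), function(i) {
    k <- sample(1:3, 1)
    vapply(seq_len(k), function(j) {
      paste0(paste(sample(syll, 2), collapse = ""), " syn ", i, j)
    }, character(1))
  })
  concepts <- tibble::tibble(id = ids, label = labels, synonyms = synonyms)
  edges <- tibble::tibble(child = ids[!is.na(parents)],
                          parent = parents[!is.na(parents)])
  ontology(concepts, edges)
}

#' Small authored respiratory ontology for the worked example
#'
#' Hand-authored concepts around the pharyngitis/pneumonia worked case:
#' a respiratory-disease root with pharyngitis, pneumonia (and its child
#' interstitial pneumonia), bronchitis and a few more distant disorders,
#' so that correct/close/incorrect hypothesis classification can all be
#' exercised.
#'
#' @return An [ontology()].
#' @export
toy_clinical_ontology <- function() {
  concepts <- tibble::tribble(
    ~id, ~label, ~synonyms,
    "respiratory_disease", "disorder of respiratory system", list("respiratory disease"),
    "upper_respiratory_infection", "upper respiratory tract infection", list("URTI"),
    "lower_respiratory_infection", "lower respiratory tract infection", list(character(0)),
    "pharyngitis", "pharyngitis", list(c("sore throat inflammation", "inflammation of the pharynx")),
    "tonsillitis", "tonsillitis", list("inflammation of the tonsils"),
    "pneumonia", "pneumonia", list(c("lung infection", "lung inflammation")),
    "interstitial_pneumonia", "interstitial pneumonia", list("interstitial lung infection"),
    "lobar_pneumonia", "lobar pneumonia", list(character(0)),
    "bronchitis", "bronchitis", list("bronchial inflammation"),
    "asthma", "asthma", list("bronchial asthma"),
    "gastroenteritis", "gastroenteritis", list("stomach flu")
  )
  concepts$synonyms <- lapply(concepts$synonyms, unlist)
  edges <- tibble::tribble(
    ~child, ~parent,
    "upper_respiratory_infection", "respiratory_disease",
    "lower_respiratory_infection", "respiratory_disease",
    "pharyngitis", "upper_respiratory_infection",
    "tonsillitis", "upper_respiratory_infection",
    "pneumonia", "lower_respiratory_infection",
    "interstitial_pneumonia", "pneumonia",
    "lobar_pneumonia", "pneumonia",
    "bronchitis", "lower_respiratory_infection",
    "asthma", "respiratory_disease"
  )
  ontology(concepts, edges)
}

#' The worked pharyngitis/pneumonia example case
#'
#' The published worked example of the binary analysis: three diagnostic
#' factors (body temperature 38.5 °C; pharynx inspection with no
#' pharyngeal erythema; chest x-ray with lobar consolidation), the two
#' hypotheses pharyngitis and pneumonia, the 3 x 2 reference grid
#' (temperature I/I, pharynx inspection D/N, chest x-ray N/I) and
#' pneumonia as the final diagnosis. Pairs with
#' [toy_clinical_ontology()].
#'
#' @return A [clinical_case()].
#' @export
table1_case <- function() {
  factors <- tibble::tribble(
    ~id, ~name, ~value, ~modality,
    "f_temp", "Body temperature", "38.5 °C", "anamnesis",
    "f_pharynx", "Pharynx inspection", "No pharyngeal erythema", "physical_exam",
    "f_xray", "Chest x-ray", "Lobar consolidation", "medical_test"
  )
  questions <- tibble::tibble(
    id = "q_fever",
    text = "Do you have a fever?",
    answer = "Yes, I measured 38.5 degrees this morning.",
    factors = list("f_temp")
  )
  exams <- tibble::tibble(
    id = "e_pharynx",
    name = "pharynx inspection",
    synonyms = list(c("throat inspection", "inspect the pharynx")),
    finding = "No pharyngeal erythema",
    factors = list("f_pharynx")
  )
  tests <- tibble::tibble(
    id = "t_xray",
    name = "chest x-ray",
    synonyms = list(c("chest radiograph", "thorax x ray")),
    finding = "Lobar consolidation",
    factors = list("f_xray")
  )
  grid <- tibble::tribble(
    ~factor, ~hypothesis, ~label,
    "f_temp", "pharyngitis", "I",
    "f_temp", "pneumonia", "I",
    "f_pharynx", "pharyngitis", "D",
    "f_pharynx", "pneumonia", "N",
    "f_xray", "pharyngitis", "N",
    "f_xray", "pneumonia", "I"
  )
  clinical_case(
    scenario = paste("A 35-year-old patient presents with cough and",
                     "malaise for three days."),
    factors = factors, questions = questions, exams = exams, tests = tests,
    hypotheses = c("pharyngitis", "pneumonia"), grid = grid,
    final_diagnosis = "pneumonia",
    review_links = c(pharyngitis = "https://example.org/topics/pharyngitis",
                     pneumonia = "https://example.org/topics/pneumonia")
  )
}

# ---- paraphrase benchmark ---------------------------------------------------

# symptom synsets: interchangeable surface forms of one clinical concept.
# Together with the question frames below they define the paraphrase
# templates: one template per symptom, paraphrases = frame x synonym.
symptom_synsets <- function() {
  list(
    fever = c("fever", "high temperature", "pyrexia"),
    cough = c("cough", "coughing fits", "persistent cough"),
    headache = c("headache", "head pain", "cephalalgia"),
    chest_pain = c("chest pain", "thoracic pain", "pain in the chest"),
    dyspnea = c("shortness of breath", "breathlessness", "dyspnea"),
    nausea = c("nausea", "urge to vomit", "queasiness"),
    fatigue = c("fatigue", "tiredness", "exhaustion"),
    dizziness = c("dizziness", "vertigo", "light headedness"),
    palpitations = c("palpitations", "racing heart", "heart pounding"),
    sweating = c("sweating", "night sweats", "excessive perspiration"),
    weight_loss = c("weight loss", "losing weight", "unintended slimming"),
    sore_throat = c("sore throat", "throat pain", "painful swallowing"),
    back_pain = c("back pain", "lumbar pain", "aching back"),
    abdominal_pain = c("abdominal pain", "belly ache", "stomach pain"),
    diarrhea = c("diarrhea", "loose stools", "watery stools"),
    constipation = c("constipation", "hard stools", "infrequent bowel movements"),
    rash = c("rash", "skin eruption", "itchy skin patches"),
    joint_pain = c("joint pain", "arthralgia", "aching joints"),
    swelling = c("leg swelling", "ankle edema", "swollen legs"),
    numbness = c("numbness", "tingling", "loss of sensation"),
    insomnia = c("insomnia", "trouble sleeping", "sleeplessness"),
    appetite_loss = c("loss of appetite", "poor appetite", "anorexia"),
    blurred_vision = c("blurred vision", "fuzzy eyesight", "unclear vision"),
    ear_pain = c("ear pain", "earache", "otalgia"),
    syncope = c("fainting", "passing out", "syncope"),
    hemoptysis = c("coughing blood", "blood in sputum", "hemoptysis"),
    dysuria = c("burning urination", "painful urination", "dysuria"),
    bruising = c("easy bruising", "frequent bruises", "skin bruising"),
    tremor = c("tremor", "shaking hands", "trembling"),
    hoarseness = c("hoarseness", "raspy voice", "voice changes"),
    heartburn = c("heartburn", "acid reflux", "burning behind the sternum"),
    leg_pain = c("calf pain", "leg cramping when walking", "pain in the calf")
  )
}

question_frames <- function() {
  c("do you have %s",
    "are you experiencing %s",
    "have you noticed %s recently",
    "do you suffer from %s",
    "has %s been bothering you",
    "did you ever complain of %s")
}

distractor_pool <- function() {
  c("what day of the week is it today",
    "can you tell me where we are right now",
    "who accompanied you here today",
    "what would you like to eat later",
    "which football team won yesterday evening")
}

#' Generate the synthetic paraphrase benchmark
#'
#' Emulates the multi-simulation question-matching evaluation protocol at
#' desk scale: each simulation draws a reference list of symptom
#' questions; paraphrases are produced by slot substitution (question
#' frame x symptom synonym); training pairs are balanced equivalent /
#' inequivalent pairs (equivalent pairs partly anchored on the canonical
#' reference phrasing, which is what the deployed ranker compares
#' against; inequivalent = across symptoms, with a sprinkle of off-topic
#' distractors); held-out test questions are paraphrase strings never
#' seen in training. Deterministic given the seed.
#'
#' @param n_simulations Number of simulated reference lists (default 6).
#' @param refs_per_sim Reference questions per simulation (default 16).
#' @param pairs Number of labeled training pairs (default 600); split
#'   50/50 between labels.
#' @param test_per_sim Held-out test questions per simulation
#'   (default 18).
#' @param seed Integer seed (default 42).
#' @param synsets Named list of symptom synonym sets (each >= 2 forms);
#'   defaults to the shipped 32-symptom list.
#' @return A list with elements `train_pairs` (tibble `question_a`,
#'   `question_b`, `equivalent`), `references` (tibble `simulation`,
#'   `id`, `text`), `test` (tibble `simulation`, `question`, `true_id`),
#'   `corpus` (character, the training-side sentences) and
#'   `synonym_pairs` (two-column tibble of within-synset word pairs for
#'   embedding supervision).
#' @export
make_paraphrase_benchmark <- function(n_simulations = 6, refs_per_sim = 16,
                                      pairs = 600, test_per_sim = 18,
                                      seed = 42L, synsets = symptom_synsets()) {
  if (length(synsets) < refs_per_sim) {
    stop("make_paraphrase_benchmark: not enough symptom templates (",
         length(synsets), ") for ", refs_per_sim, " references per simulation")
  }
  stopifnot(all(lengths(synsets) >= 2))
  withr::local_seed(seed)
  frames <- question_frames()

  phrase <- function(sym, frame_i, syn_i) {
    sprintf(frames[frame_i], synsets[[sym]][syn_i])
  }
  all_syms <- names(synsets)

  # per simulation: which symptoms are its references, and the canonical
  # reference phrasing (frame 1, synonym 1)
  references <- dplyr::bind_rows(lapply(seq_len(n_simulations), function(s) {
    syms <- sample(all_syms, refs_per_sim)
    tibble::tibble(simulation = s, id = paste0("s", s, "_", syms),
                   symptom = syms, text = vapply(syms, phrase, character(1),
                                                 frame_i = 1, syn_i = 1))
  }))

  # split the paraphrase space per symptom: combinations (frame, synonym)
  # other than the canonical (1,1); a held-out fifth goes to the test side
  combos <- tidyr::expand_grid(frame_i = seq_along(frames),
                               syn_i = seq_len(min(lengths(synsets))))
  combos <- combos[!(combos$frame_i == 1 & combos$syn_i == 1), ]
  test_combo <- sample(nrow(combos), max(3, ceiling(nrow(combos) / 5)))
  train_combos <- combos[-test_combo, ]
  test_combos <- combos[test_combo, ]

  train_phrases <- function(sym) {
    vapply(seq_len(nrow(train_combos)), function(j) {
      phrase(sym, train_combos$frame_i[j], train_combos$syn_i[j])
    }, character(1))
  }

  n_pos <- floor(pairs / 2); n_neg <- pairs - n_pos
  # half of the equivalent pairs anchor on the canonical reference phrasing
  # (that is what the deployed ranker compares against); the rest pair two
  # free paraphrases
  pos <- dplyr::bind_rows(lapply(seq_len(n_pos), function(i) {
    sym <- sample(all_syms, 1)
    if (i %% 2 == 0) {
      tibble::tibble(question_a = phrase(sym, 1, 1),
                     question_b = sample(train_phrases(sym), 1),
                     equivalent = 1L)
    } else {
      ph <- sample(train_phrases(sym), 2)
      tibble::tibble(question_a = ph[1], question_b = ph[2], equivalent = 1L)
    }
  }))
  distr <- distractor_pool()
  neg <- dplyr::bind_rows(lapply(seq_len(n_neg), function(i) {
    if (stats::runif(1) < 0.1) {
      sym <- sample(all_syms, 1)
      tibble::tibble(question_a = sample(train_phrases(sym), 1),
                     question_b = sample(distr, 1), equivalent = 0L)
    } else {
      syms <- sample(all_syms, 2)
      tibble::tibble(question_a = sample(train_phrases(syms[1]), 1),
                     question_b = sample(train_phrases(syms[2]), 1),
                     equivalent = 0L)
    }
  }))
  train_pairs <- dplyr::slice_sample(dplyr::bind_rows(pos, neg),
                                     prop = 1)

  test <- dplyr::bind_rows(lapply(seq_len(n_simulations), function(s) {
    refs <- references[references$simulation == s, ]
    rows <- lapply(seq_len(test_per_sim), function(j) {
      r <- refs[sample(nrow(refs), 1), ]
      cb <- test_combos[sample(nrow(test_combos), 1), ]
      tibble::tibble(simulation = s,
                     question = phrase(r$symptom, cb$frame_i, cb$syn_i),
                     true_id = r$id)
    })
    dplyr::bind_rows(rows)
  }))

  corpus <- unique(c(train_pairs$question_a, train_pairs$question_b,
                     references$text))
  # head word of each surface form stands for the form in the embedding;
  # heads shared by several symptoms (e.g. "pain") are ambiguous and dropped
  head_sets <- lapply(synsets, function(forms) {
    unique(vapply(strsplit(forms, " "), function(w) w[length(w)], character(1)))
  })
  head_freq <- table(unlist(head_sets))
  synonym_pairs <- dplyr::bind_rows(lapply(head_sets, function(heads) {
    heads <- heads[head_freq[heads] == 1]
    if (length(heads) < 2) return(NULL)
    tidyr::expand_grid(a = heads, b = heads) |> dplyr::filter(.data$a < .data$b)
  }))

  list(train_pairs = train_pairs,
       references = references[, c("simulation", "id", "text")],
       test = test, corpus = corpus, synonym_pairs = synonym_pairs)
}

#' Simulate learners from the BKT generating process
#'
#' Each learner starts mastered with probability `p_L0`; after every
#' opportunity an unmastered learner transitions to mastery with
#' probability `p_T`; a mastered learner answers correctly with
#' probability `1 - p_S`, an unmastered one with probability `p_G`.
#' Deterministic given the seed.
#'
#' @param params A [bkt_params()].
#' @param n_learners Number of learners (>= 1).
#' @param opportunities Opportunities per learner (>= 1).
#' @param seed Integer seed.
#' @return A long tibble `(learner, opportunity, correct)` accepted
#'   directly by [bkt_fit()].
#' @export
simulate_learners <- function(params, n_learners = 500, opportunities = 20,
                              seed = 1L) {
  stopifnot(inherits(params, "bkt_params"),
            n_learners >= 1, opportunities >= 1)
  withr::local_seed(seed)
  out <- lapply(seq_len(n_learners), function(l) {
    known <- stats::runif(1) < params$p_L0
    correct <- integer(opportunities)
    for (t in seq_len(opportunities)) {
      p_correct <- if (known) 1 - params$p_S else params$p_G
      correct[t] <- as.integer(stats::runif(1) < p_correct)
      if (!known && stats::runif(1) < params$p_T) known <- TRUE
    }
    tibble::tibble(learner = l, opportunity = seq_len(opportunities),
                   correct = correct)
  })
  dplyr::bind_rows(out)
}
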