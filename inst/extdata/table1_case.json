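{
  "scenario": "A 35-year-old patient presents with cough and malaise for three days.",
  "factors": [
    {
      "id": "f_temp",
      "name": "Body temperature",
      "value": "38.5 °C",
      "modality": "anamnesis"
    },
    {
      "id": "f_pharynx",
      "name": "Pharynx inspection",
      "value": "No pharyngeal erythema",
      "modality": "physical_exam"
    },
    {
      "id": "f_xray",
      "name": "Chest x-ray",
      "value": "Lobar consolidation",
      "modality": "medical_test"
    }
  ],
  "questions": [
    {
      "id": "q_fever",
      "text": "Do you have a fever?",
      "answer": "Yes, I measured 38.5 degrees this morning.",
      "factors": "f_temp"
    }
  ],
  "exams": [
    {
      "id": "e_pharynx",
      "name": "pharynx inspection",
      "synonyms": ["throat inspection", "inspect the pharynx"],
      "finding": "No pharyngeal erythema",
      "factors": "f_pharynx"
    }
  ],
  "tests": [
    {
      "id": "t_xray",
      "name": "chest x-ray",
      "synonyms": ["chest radiograph", "thorax x ray"],
      "finding": "Lobar consolidation",
      "factors": "f_xray"
    }
  ],
  "hypotheses": ["pharyngitis", "pneumonia"],
  "grid": [
    {
      "factor": "f_temp",
      "hypothesis": "pharyngitis",
      "label": "I"
    },
    {
      "factor": "f_temp",
      "hypothesis": "pneumonia",
      "label": "I"
    },
    {
      "factor": "f_pharynx",
      "hypothesis": "pharyngitis",
      "label": "D"
    },
    {
      "factor": "f_pharynx",
      "hypothesis": "pneumonia",
      "label": "N"
    },
    {
      "factor": "f_xray",
      "hypothesis": "pharyngitis",
      "label": "N"
    },
    {
      "factor": "f_xray",
      "hypothesis": "pneumonia",
      "label": "I"
    }
  ],
  "final_diagnosis": "pneumonia",
  "review_links": {
    "pharyngitis": "https://example.org/topics/pharyngitis",
    "pneumonia": "https://example.org/topics/pneumonia"
  }
}
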