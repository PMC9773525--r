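[
  {
    "id": "breathing_plain_hrl",
    "self_report": ["difficulty in breathing"],
    "true_disease": "fluid overload",
    "queries": [
      ["shortness of breath", true],
      ["skin rash", false],
      ["vomiting", true],
      ["abnormal appearing skin", false]
    ],
    "predicted_disease": "fluid overload"
  },
  {
    "id": "breathing_association_guided",
    "self_report": ["difficulty in breathing"],
    "true_disease": "fluid overload",
    "queries": [
      ["shortness of breath", true],
      ["vomiting", true],
      ["nausea", false],
      ["cough", false]
    ],
    "predicted_disease": "fluid overload"
  },
  {
    "id": "case_13947_plain_hrl",
    "self_report": ["arm pain"],
    "true_disease": "carpal tunnel syndrome",
    "queries": [
      ["neck pain", true],
      ["skin itching", false],
      ["skin lesion", false],
      ["skin rash", false],
      ["eye pain", false],
      ["anxiety and nervousness", false],
      ["facial pain", false],
      ["leg pain", false]
    ],
    "predicted_disease": "adhesive capsulitis of the shoulder"
  },
  {
    "id": "case_13947_association_guided",
    "self_report": ["arm pain"],
    "true_disease": "carpal tunnel syndrome",
    "queries": [
      ["ache all over", false],
      ["neck pain", true],
      ["headache", false],
      ["back pain", false],
      ["loss of sensation", true],
      ["paresthesia", false],
      ["leg pain", false]
    ],
    "predicted_disease": "carpal tunnel syndrome"
  },
  {
    "id": "case_22285_plain_hrl",
    "self_report": ["wrist pain"],
    "true_disease": "gas gangrene",
    "queries": [
      ["hand or finger pain", false],
      ["lower body pain", false],
      ["lower back pain", false],
      ["pregnancy pain", true],
      ["excessive urination at night", false],
      ["facial pain", true],
      ["skin lesion", false],
      ["abnormal appearing skin", false]
    ],
    "predicted_disease": "chancroid"
  },
  {
    "id": "case_22285_association_guided",
    "self_report": ["wrist pain"],
    "true_disease": "gas gangrene",
    "queries": [
      ["pregnancy pain", true],
      ["facial pain", true],
      ["eye pain", false],
      ["excessive urination at night", false],
      ["shoulder cramps or spasms", false],
      ["sharp abdominal pain", true]
    ],
    "predicted_disease": "gas gangrene"
  }
]
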