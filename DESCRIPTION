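Package: sidial
Title: Association-Guided Hierarchical Reinforcement Learning for Symptom
    Investigation and Disease Diagnosis Dialogues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulated disease-diagnosis dialogues driven by a two-level
    deep Q-learning policy: a controller that routes a patient to medical
    departments or triggers diagnosis, and per-department worker policies
    that investigate symptoms.  Investigation is guided by a symptom
    co-occurrence association graph that recommends contextually relevant
    symptoms and shapes rewards through recommendation and association
    critics.  Includes a synthetic patient-record generator emulating a
    multi-group disease corpus, a rule-based patient simulator, a neural
    disease classifier, dialogue evaluation metrics (success rate, average
    match rates, top-k disease coverage, group confusion) and the
    Investigation Relevance Score (IReS) for scoring how pertinent an
    agent's symptom queries are to the patient's complaints.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
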