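# Shared fixtures, all built in code.

# Four records whose status-true symptom sets are {A,B}, {A,B,C}, {A,C},
# {B,C}: the canonical small co-occurrence example (n = 2 for every pair,
# row totals 4).  Symptom D never co-occurs with anything.
four_record_dataset <- function() {
  mk <- function(id, syms) {
    list(record_id = id, disease = "dz1",
         explicit = stats::setNames(TRUE, syms[[1L]]),
         implicit = stats::setNames(rep(TRUE, length(syms) - 1L),
                                    syms[-1L]))
  }
  diag_dataset(list(mk("r1", c("A", "B")), mk("r2", c("A", "B", "C")),
                    mk("r3", c("A", "C")), mk("r4", c("B", "C"))),
               symptoms = c("A", "B", "C", "D"),
               diseases = "dz1", group_map = c(dz1 = "g1"))
}

# independent brute-force co-occurrence oracle
brute_cooccurrence <- function(dataset) {
  v <- dataset$symptoms
  n <- matrix(0L, length(v), length(v), dimnames = list(v, v))
  for (r in dataset$records) {
    st <- c(r$explicit, r$implicit)
    pres <- names(st)[st]
    if (length(pres) < 2L) next
    for (p in utils::combn(pres, 2L, simplify = FALSE)) {
      n[p[1L], p[2L]] <- n[p[1L], p[2L]] + 1L
      n[p[2L], p[1L]] <- n[p[2L], p[1L]] + 1L
    }
  }
  n
}

# Fully separable corpus: 3 groups x 3 diseases, disjoint 3-symptom
# profiles over 27 symptoms; each record reveals one profile symptom
# explicitly and the other two implicitly.
separable_dataset <- function(n_records = 90L, seed = 1L) {
  set.seed(seed)
  symptoms <- sprintf("s%02d", seq_len(27L))
  groups <- paste0("g", 1:3)
  diseases <- as.vector(vapply(1:3, function(g)
    sprintf("d%d_%d", g, 1:3), character(3)))
  group_map <- stats::setNames(rep(groups, each = 3L), diseases)
  profiles <- split(symptoms, rep(seq_len(9L), each = 3L))
  names(profiles) <- diseases
  records <- lapply(seq_len(n_records), function(k) {
    dis <- diseases[[(k - 1L) %% 9L + 1L]]
    prof <- profiles[[dis]]
    ex <- sample(prof, 1L)
    list(record_id = sprintf("r%04d", k), disease = dis,
         explicit = stats::setNames(TRUE, ex),
         implicit = stats::setNames(rep(TRUE, 2L), setdiff(prof, ex)))
  })
  diag_dataset(records, symptoms, diseases, group_map)
}

# the carpal-tunnel and gas-gangrene case records used in the printed
# case-study dialogues
case_study_records <- function() {
  v <- c("arm pain", "loss of sensation", "hand or finger pain",
         "wrist pain", "neck pain", "sharp abdominal pain",
         "pain during pregnancy", "facial pain", "fatigue", "headache",
         "skin rash", "skin lesion", "leg pain", "ache all over",
         "back pain", "paresthesia")
  rec1 <- list(record_id = "13947", disease = "carpal tunnel syndrome",
               explicit = c("arm pain" = TRUE),
               implicit = c("loss of sensation" = TRUE,
                            "hand or finger pain" = TRUE,
                            "wrist pain" = TRUE, "neck pain" = TRUE))
  rec2 <- list(record_id = "22285", disease = "gas gangrene",
               explicit = c("wrist pain" = TRUE),
               implicit = c("sharp abdominal pain" = TRUE,
                            "pain during pregnancy" = TRUE,
                            "facial pain" = TRUE, "fatigue" = TRUE))
  diseases <- c("carpal tunnel syndrome", "gas gangrene")
  diag_dataset(list(rec1, rec2), v, diseases,
               stats::setNames(c("group_6", "group_1"), diseases))
}

transcript_fixture_path <- function() {
  system.file("extdata", "case_study_transcripts.json", package = "sidial")
}

# scripted hand-built episode log (bypasses any agent)
scripted_episode <- function(self_report, queries, answers,
                             true_disease = "dz", predicted = "dz",
                             implicit_true = queries[answers],
                             ranking = predicted) {
  n <- length(queries)
  qdf <- data.frame(symptom = queries, answer = answers,
                    repetition = rep(FALSE, n), r_d = rep(0, n),
                    r_rr = rep(0, n), r_ar = rep(0, n),
                    stringsAsFactors = FALSE)
  structure(list(record_id = "scripted", self_report = self_report,
                 queries = qdf, department_activations = character(0),
                 ranking = ranking, predicted_disease = predicted,
                 true_disease = true_disease,
                 implicit_true = implicit_true,
                 success = identical(predicted, true_disease),
                 turns = length(queries),
                 reward_total = 0, terminated_by = "diagnosis"),
            class = "episode_log")
}
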