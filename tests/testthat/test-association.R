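test_that("co-occurrence counting matches a brute-force pair oracle", {
  d <- four_record_dataset()
  g <- build_cooccurrence(d)
  expect_identical(g$counts, brute_cooccurrence(d))
  expect_equal(g$counts["A", "B"], 2L)
  expect_equal(g$counts["A", "C"], 2L)
  expect_equal(g$counts["B", "C"], 2L)
  expect_equal(unname(g$row_totals[c("A", "B", "C", "D")]), c(4, 4, 4, 0))
  # and on a random generated corpus
  d2 <- generate_synthetic_dataset(
    generator_config(n_groups = 2L, diseases_per_group = 3L,
                     n_symptoms = 20L, disease_symptom_profile_size = 5L,
                     n_records = 60L, seed = 8L))
  g2 <- build_cooccurrence(d2)
  expect_identical(g2$counts, brute_cooccurrence(d2))
  expect_identical(g2$counts, t(g2$counts))
  expect_true(all(diag(g2$counts) == 0L))
})

test_that("single true symptom contributes no pairs", {
  d <- diag_dataset(list(list(record_id = "r", disease = "dz",
                              explicit = c(A = TRUE),
                              implicit = c(B = FALSE))),
                    symptoms = c("A", "B"), diseases = "dz",
                    group_map = c(dz = "g"))
  g <- build_cooccurrence(d)
  expect_true(all(g$counts == 0L))
})

test_that("association score is row-normalised and directional", {
  g <- build_cooccurrence(four_record_dataset())
  expect_equal(association_score(g, "A", "B"), 0.5)
  expect_equal(association_score(g, "A", "C"), 0.5)
  # zero-row smoothing: D never co-occurs
  expect_equal(association_score(g, "D", "A"), 0)
  expect_equal(association_score(g, "A", "D"), 0)
  expect_error(association_score(g, "A", "nope"), "unknown symptom")
  # a symptom with a single partner scores 1 on it
  d <- diag_dataset(list(list(record_id = "r", disease = "dz",
                              explicit = c(S1 = TRUE),
                              implicit = c(S2 = TRUE))),
                    symptoms = c("S1", "S2", "S3"), diseases = "dz",
                    group_map = c(dz = "g"))
  g1 <- build_cooccurrence(d)
  expect_equal(association_score(g1, "S1", "S2"), 1.0)
})

test_that("nonzero association rows sum to one exactly", {
  for (seed in 1:3) {
    d <- generate_synthetic_dataset(
      generator_config(n_groups = 2L, diseases_per_group = 2L,
                       n_symptoms = 15L, disease_symptom_profile_size = 5L,
                       n_records = 40L, seed = seed))
    g <- build_cooccurrence(d)
    for (s in g$symptoms[g$row_totals > 0]) {
      row <- vapply(g$symptoms, function(t) association_score(g, s, t), 0)
      expect_equal(sum(row), 1, tolerance = 1e-12)
    }
  }
})

test_that("context association is the sum of per-anchor scores", {
  g <- build_cooccurrence(four_record_dataset())
  expect_equal(context_association(g, "B", character(0)), 0)
  expect_equal(context_association(g, "B", "A"), 0.5)
  expect_equal(context_association(g, "B", c("A", "C")),
               association_score(g, "B", "A") +
                 association_score(g, "B", "C"))
})

test_that("top-K recommendation ranks by summed anchor-row association", {
  g <- build_cooccurrence(four_record_dataset())
  rec <- recommend_top_k(g, "A", k = 2L)
  expect_identical(rec$symptoms, c("B", "C"))   # tie broken by index
  expect_equal(rec$scores, c(0.5, 0.5))
  expect_error(recommend_top_k(g, "A", k = 0L))
  # k exceeding the candidates returns all remaining, ranked
  rec_all <- recommend_top_k(g, "A", k = 10L)
  expect_setequal(rec_all$symptoms, c("B", "C", "D"))
  expect_true(all(diff(rec_all$scores) <= 0))
  # already-confirmed symptoms are never recommended
  expect_false("A" %in% rec_all$symptoms)
})

test_that("recommendation agrees with a brute-force sort on random graphs", {
  for (seed in 1:5) {
    d <- generate_synthetic_dataset(
      generator_config(n_groups = 2L, diseases_per_group = 2L,
                       n_symptoms = 12L, disease_symptom_profile_size = 4L,
                       n_records = 30L, seed = 100L + seed))
    g <- build_cooccurrence(d)
    set.seed(seed)
    confirmed <- sample(g$symptoms, 3L)
    rec <- recommend_top_k(g, confirmed, k = 4L)
    cand <- setdiff(g$symptoms, confirmed)
    brute <- vapply(cand, function(s)
      sum(vapply(confirmed, function(a) association_score(g, a, s), 0)), 0)
    ord <- cand[order(-brute, match(cand, g$symptoms))]
    expect_identical(rec$symptoms, ord[1:4])
    expect_equal(rec$scores, unname(brute[ord[1:4]]))
  }
})

test_that("adding a confirmed symptom never lowers a candidate's score", {
  d <- generate_synthetic_dataset(
    generator_config(n_groups = 2L, diseases_per_group = 2L,
                     n_symptoms = 12L, disease_symptom_profile_size = 4L,
                     n_records = 30L, seed = 77L))
  g <- build_cooccurrence(d)
  base <- recommend_top_k(g, "symptom_001", k = 11L)
  more <- recommend_top_k(g, c("symptom_001", "symptom_002"), k = 10L)
  shared <- intersect(base$symptoms, more$symptoms)
  for (s in shared) {
    expect_gte(more$scores[match(s, more$symptoms)],
               base$scores[match(s, base$symptoms)])
  }
})

test_that("graph JSON round-trips", {
  g <- build_cooccurrence(four_record_dataset())
  p <- withr::local_tempfile(fileext = ".json")
  write_cooccurrence(g, p)
  g2 <- read_cooccurrence(p)
  expect_identical(g$counts, g2$counts)
  expect_identical(g$symptoms, g2$symptoms)
})
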