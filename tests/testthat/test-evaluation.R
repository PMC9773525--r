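test_that("success rate and means are plain episode arithmetic", {
  eps <- list(
    scripted_episode("A", c("B", "C"), c(TRUE, FALSE), "dz", "dz"),
    scripted_episode("A", c("B"), TRUE, "dz", "other"),
    scripted_episode("A", c("B", "C", "D"), c(TRUE, TRUE, FALSE), "dz",
                     "dz"),
    scripted_episode("A", character(0), logical(0), "dz", "dz"))
  expect_equal(success_rate(eps), 0.75)
  expect_equal(avg_turns(eps), (2 + 1 + 3 + 0) / 4)
  expect_equal(success_rate(eps),
               mean(vapply(eps, `[[`, NA, "success")))
  expect_error(success_rate(list()))
  one <- eps[1]
  expect_equal(avg_turns(one), 2)
  expect_equal(success_rate(one), 1)
})

test_that("avg_turns matches the printed case-study dialogue lengths", {
  trs <- read_transcripts(transcript_fixture_path())
  ids <- vapply(trs, `[[`, "", "id")
  eps <- lapply(trs[match(c("case_13947_association_guided",
                            "case_22285_association_guided"), ids)],
                sidial:::transcript_to_episode)
  expect_equal(avg_turns(eps), 6.5)   # 7- and 6-turn investigations
})

test_that("match rates follow their definitions with zero-guards", {
  # two true answers of four queries, two implicit truths
  e1 <- scripted_episode("A", c("B", "C", "D", "E"),
                         c(TRUE, FALSE, TRUE, FALSE),
                         implicit_true = c("B", "D"))
  mr <- match_rates(list(e1))
  expect_equal(unname(mr["amr"]), 50)
  expect_equal(unname(mr["amr2"]), 100)
  # all queries matched
  e2 <- scripted_episode("A", c("B", "C"), c(TRUE, TRUE),
                         implicit_true = c("B", "C", "D"))
  expect_equal(unname(match_rates(list(e2))["amr"]), 100)
  expect_equal(unname(match_rates(list(e2))["amr2"]), 2 / 3 * 100)
  # an agent that queries every implicit symptom scores AMR2 = 100
  imp <- c("B", "C", "D")
  e3 <- scripted_episode("A", c(imp, "E"), c(TRUE, TRUE, TRUE, FALSE),
                         implicit_true = imp)
  expect_equal(unname(match_rates(list(e3))["amr2"]), 100)
  # zero-query episodes leave AMR to the remaining episodes
  e0 <- scripted_episode("A", character(0), logical(0),
                         implicit_true = character(0))
  expect_equal(unname(match_rates(list(e0, e1))["amr"]), 50)
  expect_true(is.na(match_rates(list(e0))[["amr"]]))
})

test_that("IReS matches a fully manual summation on the toy graph", {
  g <- build_cooccurrence(four_record_dataset())
  # two turns: query B (answered true), then D; self-report {A}
  e <- scripted_episode("A", c("B", "D"), c(TRUE, FALSE))
  ir <- ires(list(e), g)
  # turn 1: assoc(B,A) = 2/4; turn 2: D has a zero row
  expect_equal(unname(ir["ires1"]), (2 / 4 + 0) / 2)
  expect_equal(unname(ir["ires2"]), (2 / 4 + 0) / 2)
  # confirmed set grows: query B then C (both true)
  e2 <- scripted_episode("A", c("B", "C"), c(TRUE, TRUE))
  ir2 <- ires(list(e2), g)
  expect_equal(unname(ir2["ires1"]), (0.5 + 0.5) / 2)
  expect_equal(unname(ir2["ires2"]), (0.5 + (0.5 + 0.5)) / 2)
  # pooling over episodes divides by total query turns
  both <- ires(list(e, e2), g)
  expect_equal(unname(both["ires1"]), (0.5 + 0 + 0.5 + 0.5) / 4)
  # zero-association investigations score zero
  e3 <- scripted_episode("A", c("D", "D"), c(FALSE, FALSE))
  expect_equal(unname(ires(list(e3), g)["ires1"]), 0)
  expect_equal(unname(ires(list(e3), g)["ires2"]), 0)
  # a single perfectly associated query scores 1
  d1 <- diag_dataset(list(list(record_id = "r", disease = "dz",
                               explicit = c(S1 = TRUE),
                               implicit = c(S2 = TRUE))),
                     symptoms = c("S1", "S2"), diseases = "dz",
                     group_map = c(dz = "g"))
  g1 <- build_cooccurrence(d1)
  e4 <- scripted_episode("S1", "S2", TRUE)
  expect_equal(unname(ires(list(e4), g1)["ires1"]), 1.0)
})

test_that("top-k coverage is monotone and saturates at the full ranking", {
  ranking <- c("dz2", "dz1", "dz3")
  eps <- list(
    scripted_episode("A", "B", TRUE, "dz1", "dz2", ranking = ranking),
    scripted_episode("A", "B", TRUE, "dz3", "dz3",
                     ranking = c("dz3", "dz1", "dz2")))
  expect_equal(topk_disease_coverage(eps, 1L), 50)
  expect_equal(topk_disease_coverage(eps, 2L), 100)
  expect_equal(topk_disease_coverage(eps, 3L), 100)
  cov <- vapply(1:3, function(k) topk_disease_coverage(eps, k), 0)
  expect_true(all(diff(cov) >= 0))
})

test_that("group confusion counts failed episodes by group pair", {
  gm <- c(dz1 = "g1", dz2 = "g1", dz3 = "g2")
  eps <- list(
    scripted_episode("A", "B", TRUE, "dz1", "dz1"),              # success
    scripted_episode("A", "B", TRUE, "dz1", "dz2"),              # same group
    scripted_episode("A", "B", TRUE, "dz1", "dz3"),              # cross group
    scripted_episode("A", "B", TRUE, "dz3", "dz1"))
  m <- group_confusion(eps, gm, c("g1", "g2"))
  expect_equal(sum(m), 3L)   # one success excluded
  expect_equal(m["g1", "g1"], 1L)
  expect_equal(m["g1", "g2"], 1L)
  expect_equal(m["g2", "g1"], 1L)
  # all-success sets give the zero matrix
  m0 <- group_confusion(eps[1], gm, c("g1", "g2"))
  expect_true(all(m0 == 0L))
})

test_that("episode logs survive the JSONL round trip with equal metrics", {
  g <- build_cooccurrence(four_record_dataset())
  eps <- list(
    scripted_episode("A", c("B", "C"), c(TRUE, FALSE), "dz1", "dz1",
                     implicit_true = "B", ranking = c("dz1", "dz2")),
    scripted_episode("A", c("D"), FALSE, "dz1", "dz2",
                     implicit_true = character(0),
                     ranking = c("dz2", "dz1")))
  p <- withr::local_tempfile(fileext = ".jsonl")
  write_episodes(eps, p)
  back <- read_episodes(p)
  expect_equal(success_rate(back), success_rate(eps))
  expect_equal(avg_turns(back), avg_turns(eps))
  expect_equal(match_rates(back), match_rates(eps))
  expect_equal(ires(back, g), ires(eps, g))
  expect_equal(topk_disease_coverage(back, 1L),
               topk_disease_coverage(eps, 1L))
})

test_that("evaluate_agent assembles a complete report", {
  d <- separable_dataset(18L, seed = 31L)
  ag <- train_agent(d, epochs = 2L, episodes_per_epoch = 5L, hidden = 16L,
                    updates_per_epoch = 2L, seed = 32L,
                    classifier_epochs = 10L)
  rep <- evaluate_agent(ag, d, topk = c(1L, 3L))
  expect_s3_class(rep, "metrics_report")
  expect_gte(rep$success_rate, 0)
  expect_lte(rep$success_rate, 1)
  expect_true(all(c("top1", "top3") %in% names(rep$coverage)))
  expect_lte(rep$coverage[["top1"]], rep$coverage[["top3"]])
  expect_equal(dim(rep$group_confusion), c(3L, 3L))
  expect_equal(rep$n_episodes, 18L)
  row <- metrics_as_row(rep)
  expect_equal(row$success_rate, rep$success_rate)
  # deterministic: a greedy re-evaluation reproduces the report
  rep2 <- evaluate_agent(ag, d, topk = c(1L, 3L))
  expect_equal(rep$success_rate, rep2$success_rate)
  expect_equal(rep$ires2, rep2$ires2)
})
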