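test_that("q_values are deterministic, finite and action-shaped", {
  set.seed(1)
  p <- q_policy(c("a", "b", "c"), d_in = 4L, hidden = 8L)
  x <- c(1, 0, -1, 0.5)
  v1 <- q_values(p, x)
  expect_length(v1, 3L)
  expect_named(v1, c("a", "b", "c"))
  expect_true(all(is.finite(v1)))
  expect_identical(v1, q_values(p, x))
  expect_error(q_values(p, c(1, 2)), "length")
})

test_that("epsilon-greedy selection is greedy, masked and calibrated", {
  vals <- c(1, 3, 2)
  expect_equal(select_action(vals, epsilon = 0), 2L)
  expect_equal(select_action(c(2, 2, 1), epsilon = 0), 1L)  # tie -> lowest
  expect_equal(select_action(vals, 0, mask = c(TRUE, FALSE, TRUE)), 3L)
  expect_error(select_action(vals, 0, mask = rep(FALSE, 3)), "no allowed")
  # epsilon = 1: uniform over allowed actions (99% CI at 1e5 draws)
  set.seed(42)
  draws <- replicate(1e5, select_action(c(0, 0, 0, 10), epsilon = 1))
  freq <- tabulate(draws, 4) / 1e5
  half <- 2.576 * sqrt(0.25 * 0.75 / 1e5)
  expect_true(all(abs(freq - 0.25) < half))
  # epsilon = 0.1 explores about 10% of the time
  set.seed(43)
  draws <- replicate(2e4, select_action(c(0, 0, 0, 10), epsilon = 0.1))
  explore_frac <- mean(draws != 4L) / 0.75   # 3 of 4 random picks differ
  expect_lt(abs(explore_frac - 0.10), 0.01)
})

test_that("TD targets follow the Bellman backup for DQN and Double DQN", {
  set.seed(7)
  p <- q_policy(c("a", "b"), d_in = 3L, hidden = 8L, gamma = 0.9)
  s <- diag(3)[1L, ]; s2 <- diag(3)[2L, ]
  # terminal: target is the raw reward
  b <- make_batch(list(list(s = s, a = 1L, r = 84, s2 = s2, done = TRUE)))
  expect_equal(td_targets(b, p, "dqn"), 84)
  # non-terminal: r + gamma * max target value
  b2 <- make_batch(list(list(s = s, a = 1L, r = 1, s2 = s2, done = FALSE)))
  qt <- q_values(p, s2, network = "target")
  expect_equal(td_targets(b2, p, "dqn"), 1 + 0.9 * max(qt))
  # ddqn evaluates the target net at the behaviour argmax
  qb <- q_values(p, s2)
  expect_equal(td_targets(b2, p, "ddqn"),
               1 + 0.9 * qt[[which.max(qb)]])
  # decoupling never exceeds the max: ddqn targets <= dqn targets
  set.seed(8)
  trans <- lapply(1:50, function(i)
    list(s = rnorm(3), a = 1L, r = rnorm(1), s2 = rnorm(3), done = FALSE))
  bb <- make_batch(trans)
  expect_true(all(td_targets(bb, p, "ddqn") <= td_targets(bb, p, "dqn") +
                    1e-12))
})

test_that("train_step descends the TD loss on a frozen batch", {
  set.seed(11)
  p <- q_policy(c("a", "b"), d_in = 3L, hidden = 16L, gamma = 0.9,
                lr = 0.01)
  trans <- lapply(1:20, function(i)
    list(s = rnorm(3), a = sample(2, 1), r = rnorm(1, 5),
         s2 = rnorm(3), done = TRUE))
  batch <- make_batch(trans)
  losses <- vapply(1:50, function(i) train_step(p, batch), 0)
  expect_true(all(is.finite(losses)))
  expect_lt(losses[50], losses[1])
  expect_lt(mean(diff(losses) > 0), 0.2)   # mostly non-increasing
  expect_error(train_step(p, make_batch(list())))
})

test_that("sync_target freezes the behaviour network into the target", {
  set.seed(12)
  p <- q_policy(c("a", "b"), d_in = 3L, hidden = 8L)
  batch <- make_batch(list(list(s = c(1, 0, 0), a = 1L, r = 2,
                                s2 = c(0, 1, 0), done = TRUE)))
  for (i in 1:5) train_step(p, batch)
  x <- c(0, 0, 1)
  expect_false(identical(q_values(p, x), q_values(p, x, "target")))
  sync_target(p)
  expect_identical(q_values(p, x), q_values(p, x, "target"))
  sync_target(p)   # no-op on an already-synced policy
  expect_identical(q_values(p, x), q_values(p, x, "target"))
})

test_that("Q-learning reaches the dynamic-programming fixed point on a toy
          process", {
  # deterministic 3-state chain: s1 -(a1: r=1 / a2: r=0)-> s2
  # -(a1: r=0 / a2: r=2)-> s3 (terminal).  gamma = 0.9.
  # Value iteration: Q(s2,.) = (0, 2); V(s2) = 2;
  # Q(s1,.) = (1, 0) + 0.9 * 2 = (2.8, 1.8).
  gamma <- 0.9
  R <- rbind(c(1, 0), c(0, 2))
  q_star <- matrix(0, 2, 2)
  for (it in 1:100) {
    q_new <- R
    q_new[1, ] <- R[1, ] + gamma * max(q_star[2, ])
    q_star <- q_new
  }
  expect_equal(q_star, rbind(c(2.8, 1.8), c(0, 2)))

  set.seed(21)
  p <- q_policy(c("a1", "a2"), d_in = 3L, hidden = 32L, gamma = gamma,
                lr = 0.05)
  S <- diag(3)
  trans <- list(
    list(s = S[1, ], a = 1L, r = 1, s2 = S[2, ], done = FALSE),
    list(s = S[1, ], a = 2L, r = 0, s2 = S[2, ], done = FALSE),
    list(s = S[2, ], a = 1L, r = 0, s2 = S[3, ], done = TRUE),
    list(s = S[2, ], a = 2L, r = 2, s2 = S[3, ], done = TRUE))
  batch <- make_batch(trans)
  for (it in 1:4000) {
    train_step(p, batch)
    if (it %% 25 == 0) sync_target(p)
  }
  sync_target(p)
  learned <- rbind(q_values(p, S[1, ]), q_values(p, S[2, ]))
  expect_equal(unname(learned), q_star, tolerance = 1e-2)
})

test_that("episode execution respects the hierarchy's action boundaries", {
  d <- separable_dataset(45L, seed = 2L)
  set.seed(3)
  cl <- train_classifier(d, hidden = 32L, epochs = 10L, seed = 4L)
  ag <- hierarchical_agent(d, classifier = cl, hidden = 16L)
  set.seed(5)
  for (i in 1:10) {
    el <- run_episode(ag, d$records[[i]], explore = TRUE)
    expect_lte(el$turns, ag$cfg$N)
    expect_identical(el$turns, nrow(el$queries))
    if (el$success) expect_identical(el$predicted_disease, el$true_disease)
    # masking soundness: every query lies in some activated department
    if (el$turns > 0L) {
      allowed <- unique(unlist(ag$dept_symptoms[el$department_activations]))
      expect_true(all(el$queries$symptom %in% allowed))
    }
  }
})

test_that("department action spaces mirror each group's observed symptoms", {
  d <- separable_dataset(45L, seed = 2L)
  cl <- train_classifier(d, hidden = 32L, epochs = 5L, seed = 4L)
  ag <- hierarchical_agent(d, classifier = cl, hidden = 8L)
  expect_named(ag$workers, d$groups)
  for (g in d$groups) {
    expect_length(ag$dept_symptoms[[g]], 9L)   # 3 disjoint 3-symptom profiles
    expect_identical(ag$workers[[g]]$actions,
                     c(ag$dept_symptoms[[g]], ".return"))
  }
  expect_identical(ag$controller$actions, c(d$groups, "diagnose"))
})

test_that("training is deterministic given the seed and logs per epoch", {
  d <- separable_dataset(27L, seed = 6L)
  a1 <- train_agent(d, epochs = 3L, episodes_per_epoch = 5L, hidden = 16L,
                    updates_per_epoch = 2L, seed = 9L,
                    classifier_epochs = 5L)
  a2 <- train_agent(d, epochs = 3L, episodes_per_epoch = 5L, hidden = 16L,
                    updates_per_epoch = 2L, seed = 9L,
                    classifier_epochs = 5L)
  expect_identical(a1$training_log, a2$training_log)
  expect_identical(a1$controller$net, a2$controller$net)
  expect_equal(nrow(a1$training_log), 3L)
  # zero epochs: empty log, untouched policies
  a0 <- train_agent(d, epochs = 0L, episodes_per_epoch = 5L, hidden = 16L,
                    seed = 9L, classifier_epochs = 5L)
  expect_equal(nrow(a0$training_log), 0L)
  expect_equal(a0$controller$replay_n, 0L)
})

test_that("the flat baseline diagnoses through disease actions", {
  d <- separable_dataset(27L, seed = 6L)
  ag <- train_agent(d, epochs = 2L, episodes_per_epoch = 5L, hidden = 16L,
                    updates_per_epoch = 2L, seed = 10L, flat = TRUE,
                    classifier_epochs = 5L)
  expect_length(ag$policy$actions,
                length(d$symptoms) + length(d$diseases))
  el <- run_episode(ag, d$records[[1L]], explore = FALSE)
  expect_lte(el$turns, ag$cfg$N)
  expect_true(el$terminated_by %in% c("diagnosis", "turn_limit"))
})

test_that("prediction and simulation methods wrap greedy episodes", {
  d <- separable_dataset(18L, seed = 8L)
  ag <- train_agent(d, epochs = 2L, episodes_per_epoch = 5L, hidden = 16L,
                    updates_per_epoch = 2L, seed = 11L,
                    classifier_epochs = 10L)
  pr <- predict(ag, d)
  expect_equal(nrow(pr), 18L)
  expect_true(all(c("record_id", "predicted", "true", "success",
                    "turns") %in% names(pr)))
  sims <- simulate(ag, nsim = 4L, seed = 12L, data = d)
  expect_length(sims, 4L)
  expect_s3_class(sims[[1L]], "episode_log")
})
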