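#' Deep Q-learning policy
#'
#' A value network over a fixed, ordered action space with an
#' epsilon-greedy behaviour rule, a periodically frozen target network for
#' bootstrapped TD targets, and a bounded replay buffer of transitions.
#' The policy object is environment-backed so that replay pushes and
#' gradient steps update it in place.
#'
#' @param actions character vector of action identifiers (fixed after
#'   construction).
#' @param d_in length of the state feature vector.
#' @param hidden hidden-layer width of the value network.
#' @param epsilon exploration rate of the behaviour rule.
#' @param gamma discount factor.
#' @param lr SGD learning rate.
#' @param replay_capacity maximum number of stored transitions (oldest
#'   evicted first).
#' @return An object of class `q_policy`.
#' @export
q_policy <- function(actions, d_in, hidden = 512L, epsilon = 0.1,
                     gamma = 0.9, lr = 5e-4, replay_capacity = 10000L) {
  stopifnot(length(actions) >= 1L, d_in >= 1L)
  e <- new.env(parent = emptyenv())
  e$actions <- actions
  e$d_in <- as.integer(d_in)
  e$epsilon <- epsilon
  e$gamma <- gamma
  e$lr <- lr
  e$net <- mlp_new(d_in, as.integer(hidden), length(actions))
  e$target <- e$net
  e$replay_capacity <- as.integer(replay_capacity)
  e$replay <- vector("list", replay_capacity)
  e$replay_n <- 0L
  e$replay_pos <- 0L
  class(e) <- "q_policy"
  e
}

#' @export
print.q_policy <- function(x, ...) {
  cat(sprintf(paste0("<q_policy> %d actions, input %d, hidden %d, ",
                     "epsilon %.2f, gamma %.2f, replay %d/%d\n"),
              length(x$actions), x$d_in, x$net$d_hidden, x$epsilon,
              x$gamma, x$replay_n, x$replay_capacity))
  invisible(x)
}

#' Per-action state-action values
#'
#' @param policy a [q_policy()].
#' @param state_vector numeric state vector of length `policy$d_in`.
#' @param network `"behavior"` or `"target"`.
#' @return Named numeric vector, one finite value per action.
#' @export
q_values <- function(policy, state_vector,
                     network = c("behavior", "target")) {
  network <- match.arg(network)
  if (length(state_vector) != policy$d_in)
    stop("state vector length ", length(state_vector),
         " does not match policy input ", policy$d_in)
  net <- if (network == "behavior") policy$net else policy$target
  stats::setNames(mlp_predict1(net, state_vector), policy$actions)
}

#' Epsilon-greedy action selection
#'
#' With probability `1 - epsilon` the allowed action with the highest
#' value (ties broken towards the lowest index); with probability
#' `epsilon` a uniformly random allowed action.  Uses the session RNG, so
#' selection is deterministic given the RNG state.
#'
#' @param values numeric vector of per-action values.
#' @param epsilon exploration rate.
#' @param mask optional logical vector marking allowed actions.
#' @return The selected action index.
#' @export
select_action <- function(values, epsilon = 0, mask = NULL) {
  allowed <- if (is.null(mask)) seq_along(values) else which(mask)
  if (length(allowed) == 0L) stop("no allowed action to select")
  if (epsilon > 0 && stats::runif(1L) < epsilon)
    return(allowed[[sample.int(length(allowed), 1L)]])
  allowed[[which.max(values[allowed])]]
}

#' Store a transition in a policy's replay buffer
#'
#' @param policy a [q_policy()].
#' @param s,a,r,s2,done state vector, action index, reward, next state
#'   vector and terminal flag.
#' @export
replay_push <- function(policy, s, a, r, s2, done) {
  policy$replay_pos <- policy$replay_pos %% policy$replay_capacity + 1L
  policy$replay[[policy$replay_pos]] <-
    list(s = s, a = as.integer(a), r = r, s2 = s2, done = isTRUE(done))
  policy$replay_n <- min(policy$replay_n + 1L, policy$replay_capacity)
  invisible(policy)
}

#' Sample a training batch from the replay buffer
#'
#' @param policy a [q_policy()].
#' @param n batch size (sampled with replacement).
#' @return A batch: list with matrix `S`, integer `a`, numeric `r`,
#'   matrix `S2` and logical `done`.
#' @export
replay_sample <- function(policy, n = 100L) {
  if (policy$replay_n == 0L) stop("replay buffer is empty")
  idx <- sample.int(policy$replay_n, n, replace = TRUE)
  make_batch(policy$replay[idx])
}

#' Assemble transitions into a batch
#'
#' @param transitions list of transitions as stored by [replay_push()].
#' @return A batch list (`S`, `a`, `r`, `S2`, `done`).
#' @export
make_batch <- function(transitions) {
  list(S = do.call(rbind, lapply(transitions, `[[`, "s")),
       a = vapply(transitions, `[[`, 0L, "a"),
       r = vapply(transitions, `[[`, 0, "r"),
       S2 = do.call(rbind, lapply(transitions, `[[`, "s2")),
       done = vapply(transitions, `[[`, NA, "done"))
}

#' Temporal-difference targets for a batch
#'
#' Terminal transitions get the raw reward.  Otherwise, `"dqn"` bootstraps
#' with the maximum target-network value at the next state; `"ddqn"`
#' (Double DQN) evaluates the target network at the behaviour network's
#' argmax action, decoupling selection from evaluation to curb value
#' overestimation — its targets are never larger than the DQN targets.
#'
#' @param batch a batch from [replay_sample()] or [make_batch()].
#' @param policy a [q_policy()].
#' @param mode `"dqn"` or `"ddqn"`.
#' @return Numeric vector of per-transition targets.
#' @export
td_targets <- function(batch, policy, mode = c("dqn", "ddqn")) {
  mode <- match.arg(mode)
  n <- length(batch$r)
  stopifnot(n >= 1L)
  Qt <- mlp_forward(policy$target, batch$S2)$out
  boot <- if (mode == "dqn") {
    apply(Qt, 1L, max)
  } else {
    amax <- max.col(mlp_forward(policy$net, batch$S2)$out,
                    ties.method = "first")
    Qt[cbind(seq_len(n), amax)]
  }
  batch$r + policy$gamma * boot * !batch$done
}

#' One gradient step on the TD loss
#'
#' Computes the mean squared error between the behaviour network's values
#' at the taken actions and the TD targets, applies one SGD update to the
#' behaviour network only, and returns the pre-update loss.
#'
#' @param policy a [q_policy()].
#' @param batch a batch; if `NULL`, sampled from the replay buffer.
#' @param mode `"dqn"` or `"ddqn"` target rule.
#' @param batch_size replay sample size when `batch` is `NULL`.
#' @return Scalar pre-update loss.
#' @export
train_step <- function(policy, batch = NULL, mode = "dqn",
                       batch_size = 100L) {
  if (is.null(batch)) batch <- replay_sample(policy, batch_size)
  n <- length(batch$r)
  if (n == 0L) stop("empty batch")
  y <- td_targets(batch, policy, mode)
  fwd <- mlp_forward(policy$net, batch$S)
  ia <- cbind(seq_len(n), batch$a)
  pred <- fwd$out[ia]
  loss <- mean((pred - y)^2)
  d_out <- matrix(0, n, length(policy$actions))
  d_out[ia] <- 2 * (pred - y) / n
  policy$net <- mlp_sgd(policy$net, batch$S, fwd, d_out, policy$lr)
  loss
}

#' Freeze the behaviour network into the target network
#'
#' @param policy a [q_policy()].
#' @export
sync_target <- function(policy) {
  policy$target <- policy$net
  invisible(policy)
}

## ---- hierarchical agent ----------------------------------------------------

#' Construct an untrained hierarchical diagnosis agent
#'
#' The controller policy chooses among the disease groups (departments)
#' or the diagnose action; each department owns a worker policy whose
#' actions are the symptoms observed in that group's records plus a
#' return-control action.  All policies share the state encoding of
#' [encode_state()].
#'
#' @param dataset training [diag_dataset()]; fixes vocabularies and
#'   department symptom sets.
#' @param graph co-occurrence graph (built from `dataset` if `NULL`).
#' @param classifier a [train_classifier()] model (trained on `dataset` if
#'   `NULL`).
#' @param cfg a [reward_config()].
#' @param k recommendation breadth.
#' @param hidden hidden width of every value network.
#' @param epsilon exploration rate.
#' @param lr learning rate.
#' @param replay_capacity replay size per policy.
#' @param mode `"dqn"` or `"ddqn"`.
#' @param mask_known_eval if `TRUE` (default), already-answered symptoms
#'   are masked out during greedy evaluation; during exploration they stay
#'   selectable so the repetition penalty is learnable.
#' @param diagnose_from_start if `FALSE` (default), the controller's
#'   diagnose action is masked until at least one department has been
#'   activated, so every dialogue contains an investigation phase.
#' @param flat if `TRUE`, build the flat baseline instead: a single policy
#'   whose actions are all symptoms plus all diseases.
#' @return A list of class `diag_agent`.
#' @export
hierarchical_agent <- function(dataset, graph = NULL, classifier = NULL,
                               cfg = reward_config(), k = 5L,
                               hidden = 512L, epsilon = 0.1, lr = 5e-4,
                               replay_capacity = 10000L,
                               mode = c("dqn", "ddqn"),
                               mask_known_eval = TRUE, flat = FALSE,
                               diagnose_from_start = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "diag_dataset"))
  if (is.null(graph)) graph <- build_cooccurrence(dataset)
  if (is.null(classifier)) classifier <- train_classifier(dataset)
  v <- dataset$symptoms
  d <- state_dim(length(v))
  agent <- list(symptoms = v, diseases = dataset$diseases,
                groups = dataset$groups, group_map = dataset$group_map,
                graph = graph, classifier = classifier, cfg = cfg,
                k = as.integer(k), mode = mode,
                mask_known_eval = isTRUE(mask_known_eval),
                diagnose_from_start = isTRUE(diagnose_from_start),
                flat = isTRUE(flat), epsilon = epsilon,
                training_log = NULL)
  if (flat) {
    agent$policy <- q_policy(c(v, dataset$diseases), d, hidden, epsilon,
                             cfg$gamma_w, lr, replay_capacity)
  } else {
    dept_symptoms <- lapply(dataset$groups, function(g) {
      recs <- Filter(function(r) dataset$group_map[[r$disease]] == g,
                     dataset$records)
      syms <- unique(unlist(lapply(recs, function(r)
        c(names(r$explicit), names(r$implicit)))))
      v[v %in% syms]                      # vocabulary order
    })
    names(dept_symptoms) <- dataset$groups
    agent$dept_symptoms <- dept_symptoms
    agent$controller <- q_policy(c(dataset$groups, "diagnose"), d, hidden,
                                 epsilon, cfg$gamma_c, lr, replay_capacity)
    agent$workers <- lapply(dataset$groups, function(g)
      q_policy(c(dept_symptoms[[g]], ".return"), d, hidden, epsilon,
               cfg$gamma_w, lr, replay_capacity))
    names(agent$workers) <- dataset$groups
  }
  class(agent) <- "diag_agent"
  agent
}

# score one query: critics evaluated against the pre-step context
score_query <- function(queried, state, graph, cfg, repetition, answer) {
  r_d <- internal_reward(if (repetition) "repetition"
                         else if (answer) "match" else "other", cfg)
  r_rr <- recommendation_reward(queried, state$recommended, cfg)
  as_t <- context_association(graph, queried, confirmed_set(state))
  r_ar <- association_reward(as_t, cfg)
  list(r_d = r_d, r_rr = r_rr, r_ar = r_ar,
       total = total_reward(r_d, r_rr, r_ar))
}

#' Run one simulated diagnosis dialogue
#'
#' The controller repeatedly selects a department or the diagnose action.
#' An activated department queries symptoms (earning the internal and
#' association-module critics each turn) until it returns control or the
#' global turn limit is reached; the diagnose action invokes the disease
#' classifier on the current symptom-status encoding and ends the episode.
#' With `explore = TRUE` actions are epsilon-greedy and every transition
#' is pushed to its policy's replay buffer; with `explore = FALSE` the
#' agent acts greedily and (by default) masks already-answered symptoms.
#'
#' @param agent a [hierarchical_agent()].
#' @param record the patient record to simulate.
#' @param explore logical; exploration + replay storage on/off.
#' @return An `episode_log`: list with `record_id`, `self_report`,
#'   `queries` (data frame of symptom, answer, repetition and the three
#'   critics), `department_activations`, `ranking`, `predicted_disease`,
#'   `true_disease`, `success`, `turns`, `reward_total`, `terminated_by`.
#' @export
run_episode <- function(agent, record, explore = FALSE) {
  if (agent$flat) return(run_episode_flat(agent, record, explore))
  cfg <- agent$cfg
  graph <- agent$graph
  v <- agent$symptoms
  eps <- if (explore) agent$epsilon else 0
  mask_known <- !explore && agent$mask_known_eval
  state <- dialogue_reset(record, graph, agent$k, cfg)
  queries <- list()
  activations <- character(0)
  terminated_by <- NULL
  predicted <- NA_character_
  ranking <- NULL
  success <- FALSE
  reward_total <- 0
  n_groups <- length(agent$groups)
  n_activations <- 0L
  # the most recent worker transition: the terminal diagnosis reward is
  # part of the department agent's internal critic, so it is credited
  # retroactively to the last investigation step
  last_worker <- NULL

  repeat {
    s_c <- encode_state(state, v)
    cmask <- c(rep(TRUE, n_groups),
               agent$diagnose_from_start || n_activations > 0L)
    a_c <- select_action(q_values(agent$controller, s_c), eps, cmask)
    n_activations <- n_activations + 1L
    # a worker may return control without consuming a turn, so the turn
    # limit alone cannot bound the episode; after 2N controller decisions
    # the diagnose action is forced
    if (n_activations > 2L * cfg$N) a_c <- n_groups + 1L
    if (a_c == n_groups + 1L) {           # diagnose
      ranking <- predict_disease(agent$classifier, state$status)
      predicted <- ranking$disease[[1L]]
      success <- identical(predicted, record$disease)
      r_term <- internal_reward(if (success) "success" else "failure", cfg)
      reward_total <- reward_total + r_term
      if (explore) {
        replay_push(agent$controller, s_c, a_c,
                    controller_reward(r_term, action = "diagnose"),
                    s_c, TRUE)
        if (!is.null(last_worker)) {
          tr <- last_worker$policy$replay[[last_worker$pos]]
          tr$r <- tr$r + r_term
          tr$done <- TRUE
          last_worker$policy$replay[[last_worker$pos]] <- tr
        }
      }
      terminated_by <- "diagnosis"
      break
    }
    g <- agent$groups[[a_c]]
    activations <- c(activations, g)
    worker <- agent$workers[[g]]
    dept_syms <- agent$dept_symptoms[[g]]
    n_sym <- length(dept_syms)
    worker_rd <- numeric(0)
    hit_limit <- FALSE
    repeat {
      s_w <- encode_state(state, v)
      mask <- NULL
      if (mask_known) {
        mask <- c(state$status[dept_syms] == STATUS_UNKNOWN, TRUE)
      }
      a_w <- select_action(q_values(worker, s_w), eps, mask)
      if (a_w == n_sym + 1L) {            # return control
        if (explore) replay_push(worker, s_w, a_w, 0, s_w, TRUE)
        break
      }
      queried <- dept_syms[[a_w]]
      res <- dialogue_step(state, record, queried, graph)
      # critics judge the query against the pre-step context: `state` is
      # not reassigned until after scoring
      sc <- score_query(queried, state, graph, cfg, res$repetition,
                        res$answer)
      state <- res$state
      state$last_reward <- sc$total
      queries[[length(queries) + 1L]] <-
        list(symptom = queried, answer = res$answer,
             repetition = res$repetition,
             r_d = sc$r_d, r_rr = sc$r_rr, r_ar = sc$r_ar)
      reward_total <- reward_total + sc$total
      worker_rd <- c(worker_rd, sc$r_d)
      hit_limit <- res$turn_limit
      if (hit_limit) {
        # forced termination counts as a failed diagnosis: the penalty
        # joins the department agent's internal reward stream
        r_fail <- internal_reward("failure", cfg)
        sc$total <- sc$total + r_fail
        worker_rd[length(worker_rd)] <- worker_rd[length(worker_rd)] +
          r_fail
        reward_total <- reward_total + r_fail
      }
      if (explore) {
        replay_push(worker, s_w, a_w, sc$total, encode_state(state, v),
                    hit_limit)
        last_worker <- list(policy = worker, pos = worker$replay_pos)
      }
      if (hit_limit) break
    }
    rc <- if (length(worker_rd))
      controller_reward(worker_rd, cfg$gamma_c) else 0
    if (hit_limit) {
      # a disease is still predicted for the log, but the episode fails
      ranking <- predict_disease(agent$classifier, state$status)
      predicted <- ranking$disease[[1L]]
      success <- FALSE
      terminated_by <- "turn_limit"
    }
    if (explore)
      replay_push(agent$controller, s_c, a_c, rc, encode_state(state, v),
                  hit_limit)
    if (hit_limit) break
  }

  episode_log(record, queries, activations, ranking, predicted, success,
              terminated_by, reward_total)
}

run_episode_flat <- function(agent, record, explore = FALSE) {
  cfg <- agent$cfg
  graph <- agent$graph
  v <- agent$symptoms
  eps <- if (explore) agent$epsilon else 0
  mask_known <- !explore && agent$mask_known_eval
  n_sym <- length(v)
  state <- dialogue_reset(record, graph, agent$k, cfg)
  queries <- list()
  terminated_by <- NULL
  predicted <- NA_character_
  ranking <- NULL
  success <- FALSE
  reward_total <- 0
  repeat {
    s <- encode_state(state, v)
    mask <- NULL
    if (mask_known)
      mask <- c(state$status == STATUS_UNKNOWN,
                rep(TRUE, length(agent$diseases)))
    qv <- q_values(agent$policy, s)
    a <- select_action(qv, eps, mask)
    if (a > n_sym) {                      # disease action: diagnose
      predicted <- agent$diseases[[a - n_sym]]
      success <- identical(predicted, record$disease)
      dq <- qv[seq_len(length(agent$diseases)) + n_sym]
      ranking <- data.frame(
        disease = agent$diseases[order(-dq, seq_along(dq))],
        probability = NA_real_, stringsAsFactors = FALSE)
      r_term <- internal_reward(if (success) "success" else "failure", cfg)
      reward_total <- reward_total + r_term
      if (explore) replay_push(agent$policy, s, a, r_term, s, TRUE)
      terminated_by <- "diagnosis"
      break
    }
    queried <- v[[a]]
    res <- dialogue_step(state, record, queried, graph)
    sc <- score_query(queried, state, graph, cfg, res$repetition,
                      res$answer)
    state <- res$state
    state$last_reward <- sc$total
    queries[[length(queries) + 1L]] <-
      list(symptom = queried, answer = res$answer,
           repetition = res$repetition,
           r_d = sc$r_d, r_rr = sc$r_rr, r_ar = sc$r_ar)
    reward_total <- reward_total + sc$total
    if (explore)
      replay_push(agent$policy, s, a, sc$total, encode_state(state, v),
                  res$turn_limit)
    if (res$turn_limit) {
      reward_total <- reward_total + internal_reward("failure", cfg)
      predicted <- NA_character_
      terminated_by <- "turn_limit"
      break
    }
  }
  episode_log(record, queries, character(0), ranking, predicted, success,
              terminated_by, reward_total)
}

episode_log <- function(record, queries, activations, ranking, predicted,
                        success, terminated_by, reward_total) {
  qdf <- if (length(queries)) {
    data.frame(symptom = vapply(queries, `[[`, "", "symptom"),
               answer = vapply(queries, `[[`, NA, "answer"),
               repetition = vapply(queries, `[[`, NA, "repetition"),
               r_d = vapply(queries, `[[`, 0, "r_d"),
               r_rr = vapply(queries, `[[`, 0, "r_rr"),
               r_ar = vapply(queries, `[[`, 0, "r_ar"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(symptom = character(0), answer = logical(0),
               repetition = logical(0), r_d = numeric(0),
               r_rr = numeric(0), r_ar = numeric(0))
  }
  structure(list(record_id = record$record_id,
                 self_report = names(record$explicit)[record$explicit],
                 queries = qdf,
                 department_activations = activations,
                 ranking = if (is.null(ranking)) character(0) else
                   ranking$disease,
                 predicted_disease = predicted,
                 true_disease = record$disease,
                 implicit_true = names(record$implicit)[record$implicit],
                 success = isTRUE(success),
                 turns = nrow(qdf),
                 reward_total = reward_total,
                 terminated_by = terminated_by),
            class = "episode_log")
}

#' @export
print.episode_log <- function(x, ...) {
  cat(sprintf("<episode_log> %s: %d turns, %s (true %s), %s\n",
              x$record_id, x$turns,
              ifelse(is.na(x$predicted_disease), "no prediction",
                     x$predicted_disease),
              x$true_disease,
              if (x$success) "success" else "failure"))
  invisible(x)
}

## ---- training --------------------------------------------------------------

#' Train a diagnosis dialogue agent
#'
#' The main fitting function.  Builds the co-occurrence graph and the
#' disease classifier from the training data (unless supplied), constructs
#' the hierarchical (or flat) agent, then runs the episode / update / sync
#' loop: each epoch simulates `episodes_per_epoch` exploratory dialogues
#' on records cycled through the training set, applies `updates_per_epoch`
#' replay-batch gradient steps to every policy, and freezes the target
#' networks once per epoch.  Fully deterministic given `seed`.
#'
#' @param dataset training [diag_dataset()].
#' @param epochs,episodes_per_epoch training schedule.
#' @param batch_size replay batch size per gradient step.
#' @param updates_per_epoch gradient steps per policy per epoch.
#' @param seed integer seed covering every source of randomness (network
#'   initialisation, classifier training, exploration, replay sampling).
#' @param cfg a [reward_config()] (ablation flags included).
#' @param k recommendation breadth.
#' @param hidden,epsilon,lr,replay_capacity,mode,flat,mask_known_eval
#'   passed to [hierarchical_agent()].
#' @param classifier optionally a pre-trained [train_classifier()] model.
#' @param classifier_epochs epochs for classifier training when it is
#'   trained here.
#' @param verbose print per-epoch progress.
#' @return A trained `diag_agent` with a `training_log` data frame
#'   (`epoch`, `success`, `avg_turns`, `avg_reward`, `loss`).
#' @seealso [predict.diag_agent()], [simulate.diag_agent()],
#'   [evaluate_agent()]
#' @export
train_agent <- function(dataset, epochs = 10L, episodes_per_epoch = 100L,
                        batch_size = 100L, updates_per_epoch = 5L,
                        seed = 1L, cfg = reward_config(), k = 5L,
                        hidden = 512L, epsilon = 0.1, lr = 5e-4,
                        replay_capacity = 10000L, mode = "dqn",
                        flat = FALSE, mask_known_eval = TRUE,
                        diagnose_from_start = FALSE,
                        classifier = NULL, classifier_epochs = 30L,
                        verbose = FALSE) {
  stopifnot(inherits(dataset, "diag_dataset"),
            length(dataset$records) > 0L, epochs >= 0L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  graph <- build_cooccurrence(dataset)
  if (is.null(classifier))
    classifier <- train_classifier(dataset, epochs = classifier_epochs,
                                   seed = as.integer(seed) + 1L)
  set.seed(as.integer(seed) + 2L)
  agent <- hierarchical_agent(dataset, graph, classifier, cfg, k, hidden,
                              epsilon, lr, replay_capacity, mode,
                              mask_known_eval, flat, diagnose_from_start)
  agent$seed <- as.integer(seed)
  policies <- if (flat) list(agent$policy) else
    c(list(agent$controller), agent$workers)

  log <- data.frame(epoch = integer(0), success = numeric(0),
                    avg_turns = numeric(0), avg_reward = numeric(0),
                    loss = numeric(0))
  n_rec <- length(dataset$records)
  rec_ptr <- 0L
  for (ep in seq_len(epochs)) {
    succ <- turns <- rew <- numeric(episodes_per_epoch)
    for (i in seq_len(episodes_per_epoch)) {
      rec_ptr <- rec_ptr %% n_rec + 1L
      el <- run_episode(agent, dataset$records[[rec_ptr]], explore = TRUE)
      succ[i] <- el$success
      turns[i] <- el$turns
      rew[i] <- el$reward_total
    }
    losses <- numeric(0)
    for (p in policies) {
      if (p$replay_n == 0L) next
      for (u in seq_len(updates_per_epoch))
        losses <- c(losses, train_step(p, NULL, agent$mode, batch_size))
    }
    for (p in policies) sync_target(p)
    log <- rbind(log, data.frame(epoch = ep, success = mean(succ),
                                 avg_turns = mean(turns),
                                 avg_reward = mean(rew),
                                 loss = if (length(losses))
                                   mean(losses) else NA_real_))
    if (verbose)
      message(sprintf("epoch %3d  success %.3f  turns %5.2f  reward %8.2f",
                      ep, mean(succ), mean(turns), mean(rew)))
  }
  agent$training_log <- log
  agent
}

#' @export
print.diag_agent <- function(x, ...) {
  kind <- if (x$flat) "flat policy" else
    sprintf("hierarchical (%d departments)", length(x$groups))
  cat(sprintf("<diag_agent> %s over %d symptoms / %d diseases [%s]\n",
              kind, length(x$symptoms), length(x$diseases),
              toupper(x$mode)))
  if (!is.null(x$training_log) && nrow(x$training_log)) {
    last <- x$training_log[nrow(x$training_log), ]
    cat(sprintf(paste0("  trained %d epochs; last epoch: success %.3f, ",
                       "avg turns %.2f, avg reward %.1f\n"),
                nrow(x$training_log), last$success, last$avg_turns,
                last$avg_reward))
  } else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.diag_agent <- function(object, ...) {
  print(object)
  cat(sprintf("  classifier train accuracy: %.3f\n",
              object$classifier$train_accuracy))
  cat(sprintf("  rewards: t=(%g,%g,%g,%g,%g) N=%d l=%g h=%g\n",
              object$cfg$t1, object$cfg$t2, object$cfg$t3, object$cfg$t4,
              object$cfg$t5, object$cfg$N, object$cfg$l, object$cfg$h))
  cat(sprintf("  critics: recommendation %s, association %s\n",
              object$cfg$use_recommendation_critic,
              object$cfg$use_association_critic))
  invisible(object)
}

#' Diagnose records with a trained agent
#'
#' Runs one greedy (no-exploration) dialogue per record and returns the
#' outcome table.
#'
#' @param object a trained `diag_agent`.
#' @param newdata a [diag_dataset()] or a list of patient records.
#' @param ... unused.
#' @return A data frame with one row per record: `record_id`,
#'   `predicted`, `true`, `success`, `turns`.
#' @export
predict.diag_agent <- function(object, newdata, ...) {
  records <- if (inherits(newdata, "diag_dataset")) newdata$records
             else newdata
  eps <- lapply(records, function(r) run_episode(object, r,
                                                 explore = FALSE))
  data.frame(record_id = vapply(eps, `[[`, "", "record_id"),
             predicted = vapply(eps, `[[`, "", "predicted_disease"),
             true = vapply(eps, `[[`, "", "true_disease"),
             success = vapply(eps, `[[`, NA, "success"),
             turns = vapply(eps, `[[`, 0L, "turns"),
             stringsAsFactors = FALSE)
}

#' Simulate greedy evaluation dialogues
#'
#' @param object a trained `diag_agent`.
#' @param nsim number of dialogues (records cycled from `data`).
#' @param seed optional seed for reproducibility.
#' @param data a [diag_dataset()] supplying the patient records.
#' @param explore run exploratory instead of greedy episodes.
#' @param ... unused.
#' @return A list of `episode_log`s.
#' @export
simulate.diag_agent <- function(object, nsim = NULL, seed = NULL,
                                data, ..., explore = FALSE) {
  records <- data$records
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
  }
  n <- if (is.null(nsim)) length(records) else nsim
  idx <- rep_len(seq_along(records), n)
  lapply(idx, function(i) run_episode(object, records[[i]], explore))
}

#' Plot the training curve of an agent
#'
#' @param x a trained `diag_agent`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.diag_agent <- function(x, ...) {
  log <- x$training_log
  if (is.null(log) || !nrow(log)) stop("agent has no training log")
  graphics::plot(log$epoch, log$success, type = "l",
                 xlab = "epoch", ylab = "training success rate",
                 ylim = c(0, 1), ...)
  graphics::lines(log$epoch, log$avg_turns / x$cfg$N, lty = 2)
  graphics::legend("topleft", lty = 1:2,
                   legend = c("success rate", "turns / N"), bty = "n")
  invisible(x)
}
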