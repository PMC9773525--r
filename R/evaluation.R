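#' Evaluation metrics for diagnosis dialogues
#'
#' All metrics are pure functions of episode logs, so any serialized set
#' of episodes can be re-scored offline.
#'
#' @name dialogue-metrics
NULL

#' Fraction of dialogues ending in a correct diagnosis
#'
#' @param episodes non-empty list of `episode_log`s.
#' @return Fraction in `[0, 1]`.  Dialogues stopped by the turn limit
#'   count as failures.
#' @export
success_rate <- function(episodes) {
  stopifnot(length(episodes) > 0L)
  mean(vapply(episodes, `[[`, NA, "success"))
}

#' Mean number of symptom queries per dialogue
#' @param episodes non-empty list of `episode_log`s.
#' @export
avg_turns <- function(episodes) {
  stopifnot(length(episodes) > 0L)
  mean(vapply(episodes, `[[`, 0L, "turns"))
}

#' Mean summed reward per dialogue
#' @param episodes non-empty list of `episode_log`s.
#' @export
avg_reward <- function(episodes) {
  stopifnot(length(episodes) > 0L)
  mean(vapply(episodes, `[[`, 0, "reward_total"))
}

#' Average match rates
#'
#' AMR is the mean over dialogues of `m_i / r_i`, where `m_i` counts the
#' agent's queries answered true and `r_i` all its queries; AMR2
#' normalises by `t_i`, the number of true implicit symptoms on the
#' patient's record.  Dialogues with zero queries (for AMR) or zero true
#' implicit symptoms (for AMR2) are excluded from the respective mean.
#'
#' @param episodes non-empty list of `episode_log`s.
#' @return Named numeric vector `c(amr, amr2)`, both percentages.
#' @export
match_rates <- function(episodes) {
  stopifnot(length(episodes) > 0L)
  m <- vapply(episodes, function(e) sum(e$queries$answer), 0)
  r <- vapply(episodes, `[[`, 0L, "turns")
  t_i <- vapply(episodes, function(e) length(e$implicit_true), 0L)
  amr <- if (any(r > 0)) mean(m[r > 0] / r[r > 0]) * 100 else NA_real_
  amr2 <- if (any(t_i > 0)) mean(m[t_i > 0] / t_i[t_i > 0]) * 100 else
    NA_real_
  c(amr = amr, amr2 = amr2)
}

# confirmed-set snapshots before each query turn of an episode:
# self-report plus every earlier query answered true
confirmed_snapshots <- function(episode) {
  conf <- episode$self_report
  out <- vector("list", episode$turns)
  q <- episode$queries
  for (j in seq_len(episode$turns)) {
    out[[j]] <- conf
    if (q$answer[[j]]) conf <- union(conf, q$symptom[[j]])
  }
  out
}

#' Investigation Relevance Score
#'
#' Measures how pertinent the agent's symptom queries were.  For every
#' query turn, the queried symptom's association with a set of anchor
#' symptoms is summed; IReS-1 anchors on the patient's self-report,
#' IReS-2 on all symptoms confirmed before that turn (self-report
#' included, so the anchor set grows and IReS-2 may exceed 1).  Both are
#' averaged over the total number of query turns.  The queried symptom is
#' the directional anchor of each association score, and the snapshot of
#' confirmed symptoms is taken before the turn's answer is applied, so a
#' query never anchors itself.
#'
#' @param episodes non-empty list of `episode_log`s.
#' @param graph a [build_cooccurrence()] graph over the episodes'
#'   vocabulary.
#' @return Named numeric vector `c(ires1, ires2)`.
#' @export
ires <- function(episodes, graph) {
  stopifnot(length(episodes) > 0L,
            inherits(graph, "cooccurrence_graph"))
  num1 <- num2 <- 0
  turns_total <- 0L
  for (e in episodes) {
    if (e$turns == 0L) next
    snaps <- confirmed_snapshots(e)
    for (j in seq_len(e$turns)) {
      queried <- e$queries$symptom[[j]]
      if (!(queried %in% graph$symptoms)) next  # out-of-vocabulary query
      row <- association_row(graph, queried)
      psr <- intersect(e$self_report, graph$symptoms)
      if (length(psr)) num1 <- num1 + sum(row[psr])
      ss <- intersect(snaps[[j]], graph$symptoms)
      if (length(ss)) num2 <- num2 + sum(row[ss])
    }
    turns_total <- turns_total + e$turns
  }
  if (turns_total == 0L) return(c(ires1 = NA_real_, ires2 = NA_real_))
  c(ires1 = num1 / turns_total, ires2 = num2 / turns_total)
}

#' Top-k disease coverage
#'
#' Percentage of dialogues whose true disease appears among the top `k`
#' diseases of the classifier's final ranking.  Monotone non-decreasing
#' in `k`; at `k = 1` it equals the success rate (in percent) for agents
#' that always diagnose.
#'
#' @param episodes non-empty list of `episode_log`s carrying rankings.
#' @param k ranking prefix length.
#' @export
topk_disease_coverage <- function(episodes, k = 3L) {
  stopifnot(length(episodes) > 0L)
  mean(vapply(episodes, function(e)
    e$true_disease %in% utils::head(e$ranking, k), NA)) * 100
}

#' Group-level confusion of failed diagnoses
#'
#' Counts failed dialogues by (true disease group, predicted disease
#' group); the diagonal collects wrong-disease-within-the-right-group
#' failures, the usual symptom-overlap confusion.  Turn-limited episodes
#' appear only if a disease was ultimately predicted.
#'
#' @param episodes list of `episode_log`s.
#' @param group_map named character vector mapping diseases to groups.
#' @param groups ordered group identifiers (rows/columns of the table).
#' @return Square integer matrix (rows: true group, columns: predicted).
#' @export
group_confusion <- function(episodes, group_map,
                            groups = unique(unname(group_map))) {
  m <- matrix(0L, length(groups), length(groups),
              dimnames = list(true = groups, predicted = groups))
  for (e in episodes) {
    if (e$success || is.na(e$predicted_disease)) next
    tg <- group_map[[e$true_disease]]
    pg <- group_map[[e$predicted_disease]]
    m[tg, pg] <- m[tg, pg] + 1L
  }
  m
}

#' Evaluate a trained agent on a dataset
#'
#' Runs one greedy dialogue per record and aggregates every metric.
#'
#' @param agent a trained [train_agent()] agent.
#' @param dataset evaluation [diag_dataset()].
#' @param topk ranking prefix lengths for disease coverage.
#' @return A list of class `metrics_report` with `success_rate`,
#'   `avg_reward`, `avg_turns`, `amr`, `amr2`, `dc_accuracy` (classifier
#'   accuracy on fully revealed records, percent), `ires1`, `ires2`,
#'   `coverage` (named by k), `group_confusion`, `n_episodes`, and the
#'   episode list itself as attribute `"episodes"`.
#' @export
evaluate_agent <- function(agent, dataset, topk = c(3L, 5L)) {
  stopifnot(inherits(dataset, "diag_dataset"),
            length(dataset$records) > 0L)
  episodes <- lapply(dataset$records, function(r)
    run_episode(agent, r, explore = FALSE))
  mr <- match_rates(episodes)
  ir <- ires(episodes, agent$graph)
  dc <- mean(vapply(dataset$records, function(r) {
    pd <- predict_disease(agent$classifier,
                          record_status(r, agent$symptoms))
    identical(pd$disease[[1L]], r$disease)
  }, NA)) * 100
  cov <- vapply(topk, function(k) topk_disease_coverage(episodes, k), 0)
  names(cov) <- paste0("top", topk)
  rep <- structure(list(success_rate = success_rate(episodes),
                        avg_reward = avg_reward(episodes),
                        avg_turns = avg_turns(episodes),
                        amr = unname(mr[["amr"]]),
                        amr2 = unname(mr[["amr2"]]),
                        dc_accuracy = dc,
                        ires1 = unname(ir[["ires1"]]),
                        ires2 = unname(ir[["ires2"]]),
                        coverage = cov,
                        group_confusion = group_confusion(
                          episodes, agent$group_map, agent$groups),
                        n_episodes = length(episodes)),
                   class = "metrics_report")
  attr(rep, "episodes") <- episodes
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Diagnosis dialogue evaluation\n")
  cat(sprintf("  episodes:      %d\n", x$n_episodes))
  cat(sprintf("  success rate:  %.4f\n", x$success_rate))
  cat(sprintf("  avg turns:     %.2f\n", x$avg_turns))
  cat(sprintf("  avg reward:    %.2f\n", x$avg_reward))
  cat(sprintf("  AMR / AMR2:    %.2f%% / %.2f%%\n", x$amr, x$amr2))
  cat(sprintf("  DC accuracy:   %.2f%%\n", x$dc_accuracy))
  cat(sprintf("  IReS-1 / -2:   %.4f / %.4f\n", x$ires1, x$ires2))
  for (nm in names(x$coverage))
    cat(sprintf("  coverage %-5s %.2f%%\n", paste0(nm, ":"),
                x$coverage[[nm]]))
  invisible(x)
}

#' Flatten a metrics report to a single-row data frame
#'
#' @param x a `metrics_report`.
#' @return One-row data frame (confusion matrix omitted).
#' @export
metrics_as_row <- function(x) {
  stopifnot(inherits(x, "metrics_report"))
  row <- data.frame(success_rate = x$success_rate,
                    avg_reward = x$avg_reward, avg_turns = x$avg_turns,
                    amr = x$amr, amr2 = x$amr2,
                    dc_accuracy = x$dc_accuracy,
                    ires1 = x$ires1, ires2 = x$ires2,
                    n_episodes = x$n_episodes)
  for (nm in names(x$coverage)) row[[paste0("coverage_", nm)]] <-
      x$coverage[[nm]]
  row
}

## ---- episode serialization -------------------------------------------------

#' Write episode logs as JSON lines
#'
#' One JSON object per line, recomputable into every metric by
#' [read_episodes()].
#'
#' @param episodes list of `episode_log`s.
#' @param path output path.
#' @export
write_episodes <- function(episodes, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (e in episodes) {
    obj <- unclass(e)
    obj$queries <- lapply(seq_len(nrow(e$queries)), function(i)
      as.list(e$queries[i, ]))
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                null = "null", na = "null"), con)
  }
  invisible(path)
}

#' @rdname write_episodes
#' @export
read_episodes <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    q <- obj$queries
    qdf <- data.frame(
      symptom = vapply(q, function(x) as.character(x$symptom), ""),
      answer = vapply(q, function(x) isTRUE(x$answer), NA),
      repetition = vapply(q, function(x) isTRUE(x$repetition), NA),
      r_d = vapply(q, function(x) as.numeric(x$r_d), 0),
      r_rr = vapply(q, function(x) as.numeric(x$r_rr), 0),
      r_ar = vapply(q, function(x) as.numeric(x$r_ar), 0),
      stringsAsFactors = FALSE)
    structure(list(record_id = obj$record_id,
                   self_report = as.character(unlist(obj$self_report)),
                   queries = qdf,
                   department_activations =
                     as.character(unlist(obj$department_activations)),
                   ranking = as.character(unlist(obj$ranking)),
                   predicted_disease =
                     if (is.null(obj$predicted_disease)) NA_character_
                     else obj$predicted_disease,
                   true_disease = obj$true_disease,
                   implicit_true = as.character(unlist(obj$implicit_true)),
                   success = isTRUE(obj$success),
                   turns = nrow(qdf),
                   reward_total = as.numeric(obj$reward_total),
                   terminated_by = obj$terminated_by),
              class = "episode_log")
  })
}

## ---- transcript scoring ----------------------------------------------------

#' Read transcript fixtures
#'
#' A transcript file is a JSON list of objects with keys `self_report`
#' (list of symptoms), `true_disease`, `queries` (list of
#' `[symptom, answer]` pairs) and `predicted_disease` — the printed
#' case-study dialogue format.
#'
#' @param path JSON file path.
#' @return List of transcript lists.
#' @export
read_transcripts <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(obj, function(tr) {
    list(id = if (is.null(tr$id)) NA_character_ else as.character(tr$id),
         self_report = as.character(unlist(tr$self_report)),
         true_disease = as.character(tr$true_disease),
         queries = lapply(tr$queries, function(q)
           list(symptom = as.character(q[[1L]]),
                answer = isTRUE(q[[2L]]))),
         predicted_disease = as.character(tr$predicted_disease))
  })
}

transcript_to_episode <- function(tr) {
  n <- length(tr$queries)
  qdf <- data.frame(
    symptom = vapply(tr$queries, `[[`, "", "symptom"),
    answer = vapply(tr$queries, `[[`, NA, "answer"),
    repetition = rep(FALSE, n),
    r_d = rep(NA_real_, n), r_rr = rep(NA_real_, n),
    r_ar = rep(NA_real_, n), stringsAsFactors = FALSE)
  structure(list(record_id = NA_character_,
                 self_report = tr$self_report,
                 queries = qdf,
                 department_activations = character(0),
                 ranking = tr$predicted_disease,
                 predicted_disease = tr$predicted_disease,
                 true_disease = tr$true_disease,
                 implicit_true = qdf$symptom[qdf$answer],
                 success = identical(tr$predicted_disease,
                                     tr$true_disease),
                 turns = n,
                 reward_total = NA_real_,
                 terminated_by = "diagnosis"),
            class = "episode_log")
}

#' Score externally supplied dialogue transcripts
#'
#' Computes per-transcript turn counts, match rate, success, and (when a
#' co-occurrence graph is given) the per-transcript IReS-1/IReS-2 scores.
#' This is how printed case-study dialogues can be scored without
#' re-running an agent.
#'
#' @param transcripts list from [read_transcripts()] (or a single
#'   transcript list).
#' @param graph optional [build_cooccurrence()] graph covering the
#'   transcript symptoms; without it the IReS columns are `NA`.
#' @return Data frame with one row per transcript: `turns`, `match_rate`,
#'   `success`, `ires1`, `ires2`.
#' @export
score_transcripts <- function(transcripts, graph = NULL) {
  if (!is.null(transcripts$queries)) transcripts <- list(transcripts)
  rows <- lapply(transcripts, function(tr) {
    e <- transcript_to_episode(tr)
    ir <- if (is.null(graph)) c(ires1 = NA_real_, ires2 = NA_real_)
          else ires(list(e), graph)
    data.frame(id = tr$id %||% NA_character_,
               turns = e$turns,
               match_rate = if (e$turns) mean(e$queries$answer) else
                 NA_real_,
               success = e$success,
               ires1 = unname(ir[["ires1"]]),
               ires2 = unname(ir[["ires2"]]))
  })
  do.call(rbind, rows)
}
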