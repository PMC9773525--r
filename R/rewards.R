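#' Reward configuration
#'
#' Shaping constants for the three critics and the two discount factors.
#' Defaults are the standard settings: `t1..t5 = 3, 2, 2, 15, 2`, turn
#' limit `N = 28`, controller discount 0.9 and worker discount 0.95.  The
#' association thresholds `l` (lower) and `h` (desired) bound the middle
#' reward band of the association critic; their defaults (0.05, 0.20) make
#' the middle band reachable at typical co-occurrence association
#' magnitudes.
#'
#' @param t1,t2,t3,t4,t5 shaping scalars: success, match and repetition
#'   terms are scaled by `N`; `t4`/`t5` are the flat recommendation and
#'   association rewards/penalties.
#' @param N maximum number of symptom queries per dialogue.
#' @param l,h lower and desired association thresholds, `0 <= l < h`.
#' @param gamma_c,gamma_w controller and worker discount factors in (0, 1].
#' @param use_recommendation_critic,use_association_critic ablation flags;
#'   disabling both yields the plain hierarchical agent without the
#'   association module.
#' @return A list of class `reward_config`.
#' @export
reward_config <- function(t1 = 3, t2 = 2, t3 = 2, t4 = 15, t5 = 2,
                          N = 28L, l = 0.05, h = 0.20,
                          gamma_c = 0.9, gamma_w = 0.95,
                          use_recommendation_critic = TRUE,
                          use_association_critic = TRUE) {
  stopifnot(N >= 1L, l >= 0, l < h,
            gamma_c > 0, gamma_c <= 1, gamma_w > 0, gamma_w <= 1)
  structure(list(t1 = t1, t2 = t2, t3 = t3, t4 = t4, t5 = t5,
                 N = as.integer(N), l = l, h = h,
                 gamma_c = gamma_c, gamma_w = gamma_w,
                 use_recommendation_critic = isTRUE(use_recommendation_critic),
                 use_association_critic = isTRUE(use_association_critic)),
            class = "reward_config")
}

#' Internal critic
#'
#' Task-completion reward of the department (worker) agent and terminal
#' reward of the dialogue: `+t1*N` on a successful diagnosis, `+t2*N` when
#' a query is answered true (a match), `-t3*N` on a repeated query, 0
#' otherwise.  A failed diagnosis (wrong disease or turn limit) earns
#' `-t1*N`, mirroring the success magnitude.
#'
#' @param event one of `"success"`, `"failure"`, `"match"`, `"repetition"`,
#'   `"other"`.
#' @param cfg a [reward_config()].
#' @return A scalar reward.
#' @export
internal_reward <- function(event = c("success", "failure", "match",
                                      "repetition", "other"),
                            cfg = reward_config()) {
  event <- match.arg(event)
  switch(event,
         success    =  cfg$t1 * cfg$N,
         failure    = -cfg$t1 * cfg$N,
         match      =  cfg$t2 * cfg$N,
         repetition = -cfg$t3 * cfg$N,
         other      = 0)
}

#' Recommendation critic
#'
#' `+t4` when the queried symptom is among the currently recommended
#' symptoms, `-t5` otherwise (including when the recommendation set is
#' empty).  Returns 0 when the critic is ablated.
#'
#' @param queried symptom identifier.
#' @param recommended a `symptom_recommendation` (or character vector).
#' @param cfg a [reward_config()].
#' @export
recommendation_reward <- function(queried, recommended,
                                  cfg = reward_config()) {
  if (!cfg$use_recommendation_critic) return(0)
  rs <- if (inherits(recommended, "symptom_recommendation"))
    recommended$symptoms else recommended
  if (length(rs) && queried %in% rs) cfg$t4 else -cfg$t5
}

#' Association critic
#'
#' Banded reward on the context association score `as_t` of the queried
#' symptom with the confirmed set: `+t4` above the desired threshold `h`,
#' `+1` in the middle band `l < as_t <= h`, `-t5` at or below `l`.
#' Returns 0 when the critic is ablated.
#'
#' @param as_t non-negative context association score
#'   (see [context_association()]).
#' @param cfg a [reward_config()].
#' @export
association_reward <- function(as_t, cfg = reward_config()) {
  stopifnot(as_t >= 0)
  if (!cfg$use_association_critic) return(0)
  if (as_t > cfg$h) cfg$t4
  else if (as_t > cfg$l) 1
  else -cfg$t5
}

#' Total shaped reward of a worker turn
#'
#' `r = r_d + (r_rr + r_ar)`: the internal critic plus the two association-
#' module shaping critics.  Ablations are handled inside the critic
#' functions (an ablated critic contributes 0, so the no-association-module
#' agent's total reward equals the internal reward exactly).
#'
#' @param r_d,r_rr,r_ar the three critic values.
#' @export
total_reward <- function(r_d, r_rr, r_ar) r_d + (r_rr + r_ar)

#' Controller reward for a department activation
#'
#' A department activation is credited with the discounted sum of the
#' per-turn internal rewards its worker earned,
#' \eqn{\sum_{i=1}^{n} \gamma_c^i r_i}; the diagnose action is credited
#' with the raw terminal reward (a single value, undiscounted).
#'
#' @param worker_rewards non-empty numeric vector of per-turn rewards
#'   (length 1 for a diagnose action: the terminal reward).
#' @param gamma_c controller discount factor.
#' @param action `"department"` (discounted sum) or `"diagnose"` (raw
#'   terminal reward).
#' @export
controller_reward <- function(worker_rewards, gamma_c = 0.9,
                              action = c("department", "diagnose")) {
  action <- match.arg(action)
  if (length(worker_rewards) == 0L)
    stop("a department activation must contain at least one worker turn")
  if (action == "diagnose") return(worker_rewards[[1L]])
  sum(gamma_c ^ seq_along(worker_rewards) * worker_rewards)
}

# largest attainable |total reward| under cfg; used to scale the reward
# feature of the state encoding into [-1, 1]
reward_scale <- function(cfg) {
  max(cfg$t1 * cfg$N,
      cfg$t2 * cfg$N + 2 * cfg$t4,
      cfg$t3 * cfg$N + 2 * cfg$t5)
}
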