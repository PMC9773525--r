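#' Dialogue environment: patient simulator and state tracker
#'
#' The simulated patient answers symptom queries from a sampled diagnosis
#' case; the state tracker records three-valued symptom statuses
#' (true/false/unknown), the turn counter, the last agent action, the
#' current top-K symptom recommendations and the last reward.  Symptom
#' statuses only ever move from unknown to true or false within an
#' episode.
#'
#' @name dialogue-environment
NULL

STATUS_TRUE <- 1L
STATUS_UNKNOWN <- 0L
STATUS_FALSE <- -1L

#' Start a dialogue episode
#'
#' Initialises the tracked state from a patient record: every explicit
#' (self-report) symptom takes its recorded status, everything else is
#' unknown, the turn counter is 0, and the first recommendations are
#' computed from the initial confirmed set.
#'
#' @param record a patient record from a [diag_dataset()].
#' @param graph a [build_cooccurrence()] graph over the same vocabulary.
#' @param k recommendation breadth (top-K symptoms).
#' @param cfg a [reward_config()]; supplies the turn limit and reward
#'   scaling used by [encode_state()].
#' @return A list of class `dialogue_state`.
#' @export
dialogue_reset <- function(record, graph, k = 5L, cfg = reward_config()) {
  v <- graph$symptoms
  status <- stats::setNames(rep(STATUS_UNKNOWN, length(v)), v)
  ex <- record$explicit
  status[names(ex)] <- ifelse(ex, STATUS_TRUE, STATUS_FALSE)
  st <- structure(list(status = status, turn = 0L,
                       last_action = NA_character_,
                       recommended = NULL, last_reward = 0,
                       k = as.integer(k), cfg = cfg,
                       terminated = FALSE),
                  class = "dialogue_state")
  st$recommended <- recommend_top_k(graph, confirmed_set(st), k)
  st
}

#' Confirmed (status-true) symptoms of a dialogue state
#'
#' @param state a `dialogue_state`.
#' @return Character vector of symptoms with status true, self-report
#'   included.
#' @export
confirmed_set <- function(state) {
  names(state$status)[state$status == STATUS_TRUE]
}

#' Patient simulator response
#'
#' Pure function of the record: returns the recorded status when the
#' queried symptom appears among the record's explicit or implicit
#' symptoms, and `FALSE` otherwise — a symptom the patient does not have on
#' file is denied.
#'
#' @param record a patient record.
#' @param queried symptom identifier.
#' @param vocabulary optional symptom vocabulary for validation.
#' @return `TRUE` or `FALSE`.
#' @export
respond <- function(record, queried, vocabulary = NULL) {
  if (!is.null(vocabulary) && !(queried %in% vocabulary))
    stop("unknown symptom identifier: ", queried)
  known <- c(record$explicit, record$implicit)
  if (queried %in% names(known)) unname(known[[queried]]) else FALSE
}

#' Advance the dialogue by one symptom query
#'
#' Applies the patient's answer to the tracked state.  Re-querying a
#' symptom whose status is already known leaves the state's statuses
#' unchanged and raises the repetition flag (the penalty is the internal
#' critic's job); either way the turn counter advances and the
#' recommendations are recomputed from the updated confirmed set.
#'
#' @param state a `dialogue_state`.
#' @param record the episode's patient record.
#' @param queried symptom to ask about.
#' @param graph the co-occurrence graph.
#' @return A list with elements `state` (updated), `answer` (logical),
#'   `repetition` (logical) and `turn_limit` (TRUE once the configured
#'   maximum number of queries is reached).
#' @export
dialogue_step <- function(state, record, queried, graph) {
  if (isTRUE(state$terminated)) stop("cannot step a terminated episode")
  check_symptoms(graph, queried)
  repetition <- state$status[[queried]] != STATUS_UNKNOWN
  answer <- if (repetition) state$status[[queried]] == STATUS_TRUE
            else respond(record, queried)
  if (!repetition)
    state$status[[queried]] <- if (answer) STATUS_TRUE else STATUS_FALSE
  state$turn <- state$turn + 1L
  state$last_action <- queried
  state$recommended <- recommend_top_k(graph, confirmed_set(state), state$k)
  list(state = state, answer = answer, repetition = repetition,
       turn_limit = state$turn >= state$cfg$N)
}

#' Length of the state feature vector
#'
#' @param n_symptoms size of the symptom vocabulary.
#' @return `5 * n_symptoms + 2`: a 3-way status indicator per symptom, a
#'   one-hot of the last queried symptom, a K-hot of the current
#'   recommendations, the normalised turn and the scaled last reward.
#' @export
state_dim <- function(n_symptoms) 5L * as.integer(n_symptoms) + 2L

#' Encode a dialogue state as a fixed-length numeric vector
#'
#' Deterministic layout over a vocabulary of `V` symptoms:
#' positions `1..3V` hold a true/false/unknown indicator triple per
#' symptom (vocabulary order); `3V+1..4V` a one-hot of the last queried
#' symptom; `4V+1..5V` a K-hot of the currently recommended symptoms;
#' `5V+1` the turn scaled by the turn limit `N`; `5V+2` the last reward
#' scaled into `[-1, 1]` by the largest attainable reward magnitude.
#'
#' @param state a `dialogue_state`.
#' @param vocabulary symptom vocabulary fixing the index layout.
#' @return Numeric vector of length [state_dim()].
#' @export
encode_state <- function(state, vocabulary = names(state$status)) {
  v <- length(vocabulary)
  status <- state$status[vocabulary]
  tri <- matrix(0, nrow = 3L, ncol = v)
  tri[1L, status == STATUS_TRUE] <- 1
  tri[2L, status == STATUS_FALSE] <- 1
  tri[3L, status == STATUS_UNKNOWN] <- 1
  last <- numeric(v)
  if (!is.na(state$last_action))
    last[match(state$last_action, vocabulary)] <- 1
  rec <- numeric(v)
  if (!is.null(state$recommended) && length(state$recommended$symptoms))
    rec[match(state$recommended$symptoms, vocabulary)] <- 1
  c(as.numeric(tri), last, rec,
    state$turn / state$cfg$N,
    state$last_reward / reward_scale(state$cfg))
}

# encode a (possibly partial) symptom-status vector for the disease
# classifier: 3V one-hot triples, same order as encode_state's status block
encode_status_onehot <- function(status, vocabulary) {
  status <- status[vocabulary]
  tri <- matrix(0, nrow = 3L, ncol = length(vocabulary))
  tri[1L, status == STATUS_TRUE] <- 1
  tri[2L, status == STATUS_FALSE] <- 1
  tri[3L, status == STATUS_UNKNOWN] <- 1
  as.numeric(tri)
}

# fully-revealed status vector of a record (training encoding for the
# classifier): explicit and implicit statuses as recorded, rest unknown
record_status <- function(record, vocabulary) {
  status <- stats::setNames(rep(STATUS_UNKNOWN, length(vocabulary)),
                            vocabulary)
  known <- c(record$explicit, record$implicit)
  if (length(known))
    status[names(known)] <- ifelse(known, STATUS_TRUE, STATUS_FALSE)
  status
}
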