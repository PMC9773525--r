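#' Symptom co-occurrence association graph
#'
#' The association module is built from a symptom-symptom co-occurrence
#' graph: nodes are symptoms, and the edge weight between two symptoms is
#' the number of patient records in which both were present (status true).
#' The directional association score from `s_i` to `s_j` is the row-
#' normalised count
#' \deqn{Association(S_i, S_j) = n(S_i, S_j) / \sum_k n(S_i, S_k),}
#' i.e. the empirical chance of seeing `s_j` among the companions of
#' `s_i`.  Only status-true symptoms (explicit or implicit) co-occur;
#' negated or unknown findings contribute nothing, and a symptom is never
#' its own companion.
#'
#' @param dataset a [diag_dataset()] (typically the training split, to
#'   avoid leaking test statistics into the investigation policy).
#' @return An object of class `cooccurrence_graph`: list with `symptoms`
#'   (the vocabulary), `counts` (symmetric integer matrix, zero diagonal)
#'   and `row_totals`.
#' @export
build_cooccurrence <- function(dataset) {
  stopifnot(inherits(dataset, "diag_dataset"))
  v <- dataset$symptoms
  counts <- matrix(0L, length(v), length(v), dimnames = list(v, v))
  for (r in dataset$records) {
    status <- c(r$explicit, r$implicit)
    pres <- names(status)[status]
    if (length(pres) >= 2L) {
      i <- match(pres, v)
      counts[i, i] <- counts[i, i] + 1L
    }
  }
  diag(counts) <- 0L
  new_cooccurrence(v, counts)
}

new_cooccurrence <- function(symptoms, counts) {
  stopifnot(is.matrix(counts), nrow(counts) == length(symptoms),
            ncol(counts) == length(symptoms))
  if (any(counts != t(counts))) stop("co-occurrence counts must be symmetric")
  if (any(diag(counts) != 0)) stop("co-occurrence diagonal must be zero")
  structure(list(symptoms = symptoms,
                 counts = counts,
                 row_totals = rowSums(counts)),
            class = "cooccurrence_graph")
}

#' @export
print.cooccurrence_graph <- function(x, ...) {
  cat(sprintf("<cooccurrence_graph> %d symptoms, %d co-occurring pairs\n",
              length(x$symptoms), sum(x$counts[upper.tri(x$counts)] > 0)))
  invisible(x)
}

check_symptoms <- function(graph, s) {
  bad <- setdiff(s, graph$symptoms)
  if (length(bad)) stop("unknown symptom identifier: ", bad[[1L]])
}

#' Directional association score between two symptoms
#'
#' @param graph a [build_cooccurrence()] graph.
#' @param s_i anchor symptom; the score is normalised by `s_i`'s row total,
#'   so `association_score(g, a, b)` and `association_score(g, b, a)`
#'   generally differ.
#' @param s_j companion symptom.
#' @return `n(s_i, s_j) / row_total(s_i)` in `[0, 1]`; 0 when `s_i` never
#'   co-occurs with anything (zero-row smoothing).
#' @export
association_score <- function(graph, s_i, s_j) {
  check_symptoms(graph, c(s_i, s_j))
  tot <- graph$row_totals[[s_i]]
  if (tot == 0) return(0)
  graph$counts[s_i, s_j] / tot
}

# vectorised row of association scores from anchor s_i to all symptoms
association_row <- function(graph, s_i) {
  tot <- graph$row_totals[[s_i]]
  if (tot == 0) return(stats::setNames(numeric(length(graph$symptoms)),
                                       graph$symptoms))
  graph$counts[s_i, ] / tot
}

#' Context association of a queried symptom with the confirmed set
#'
#' The association critic's raw signal: the summed association of the
#' currently queried symptom with every already-confirmed symptom
#' (self-report included), \eqn{as_t = \sum_k Association(Sym_t, SS_k)}.
#'
#' @param graph a co-occurrence graph.
#' @param queried the symptom being asked about (anchor of each score).
#' @param confirmed character vector of confirmed (status-true) symptoms.
#' @return Non-negative score; 0 for an empty confirmed set.
#' @export
context_association <- function(graph, queried, confirmed) {
  check_symptoms(graph, c(queried, confirmed))
  if (length(confirmed) == 0L) return(0)
  sum(association_row(graph, queried)[confirmed])
}

#' Top-K symptom recommendation
#'
#' Ranks every not-yet-confirmed symptom `s` by
#' \eqn{\sum_{j} Association(SS_j, s)} — each confirmed symptom is the
#' anchor (row) of its contribution — and returns the `k` best.  Ties are
#' broken by vocabulary index so recommendations are deterministic.  With
#' an empty confirmed set the ranking falls back to global co-occurrence
#' frequency (column sums over all rows).
#'
#' @param graph a co-occurrence graph.
#' @param confirmed character vector of confirmed symptoms (excluded from
#'   the candidates).
#' @param k number of symptoms to recommend; if fewer candidates remain,
#'   all are returned.
#' @return A list of class `symptom_recommendation` with `symptoms`
#'   (ordered identifiers) and `scores` (non-increasing).
#' @export
recommend_top_k <- function(graph, confirmed, k = 5L) {
  stopifnot(k >= 1L)
  check_symptoms(graph, confirmed)
  v <- graph$symptoms
  if (length(confirmed) == 0L) {
    scores <- colSums(graph$counts)
    scores <- if (sum(scores) > 0) scores / sum(scores) else
      stats::setNames(numeric(length(v)), v)
  } else {
    rows <- vapply(confirmed, function(s) association_row(graph, s),
                   numeric(length(v)))
    scores <- rowSums(rows)
    names(scores) <- v
  }
  cand <- setdiff(v, confirmed)
  scores <- scores[cand]
  ord <- order(-scores, match(cand, v))
  take <- seq_len(min(k, length(cand)))
  sel <- ord[take]
  structure(list(symptoms = cand[sel], scores = unname(scores[sel])),
            class = "symptom_recommendation")
}

#' @export
print.symptom_recommendation <- function(x, ...) {
  cat("<symptom_recommendation>\n")
  for (i in seq_along(x$symptoms))
    cat(sprintf("  %2d. %-24s %.4f\n", i, x$symptoms[[i]], x$scores[[i]]))
  invisible(x)
}

#' Persist a co-occurrence graph as JSON
#'
#' Sparse representation: vocabulary plus `[i, j, n]` triples (1-based
#' upper-triangle indices).
#'
#' @param graph a co-occurrence graph.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cooccurrence <- function(graph, path) {
  idx <- which(upper.tri(graph$counts) & graph$counts > 0, arr.ind = TRUE)
  triples <- lapply(seq_len(nrow(idx)), function(r)
    c(idx[r, 1L], idx[r, 2L], graph$counts[idx[r, 1L], idx[r, 2L]]))
  obj <- list(counts = triples, symptoms = as.list(graph$symptoms))
  writeLines(jsonlite::toJSON(obj, auto_unbox = FALSE, digits = NA), path,
             useBytes = TRUE)
  invisible(path)
}

#' @rdname write_cooccurrence
#' @export
read_cooccurrence <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  v <- vapply(obj$symptoms, as.character, "")
  counts <- matrix(0L, length(v), length(v), dimnames = list(v, v))
  for (tr in obj$counts) {
    i <- as.integer(tr[[1L]]); j <- as.integer(tr[[2L]])
    counts[i, j] <- counts[j, i] <- as.integer(tr[[3L]])
  }
  new_cooccurrence(v, counts)
}
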