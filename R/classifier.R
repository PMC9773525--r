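#' Train the disease classifier
#'
#' A two-layer feed-forward network (one rectified hidden layer, softmax
#' output) mapping the one-hot symptom-status encoding (true/false/unknown
#' triple per symptom, length `3 * |symptoms|`) to a probability
#' distribution over all diseases.  Trained by mini-batch SGD on
#' cross-entropy with every record encoded as if all its recorded symptoms
#' had been revealed; symptoms absent from a record stay "unknown", which
#' preserves the distinction partial observation creates at dialogue time.
#'
#' @param dataset a [diag_dataset()] (normally the training split).
#' @param hidden hidden-layer width.
#' @param epochs passes over the data.
#' @param lr SGD learning rate.
#' @param momentum classical momentum coefficient (0 disables).
#' @param negative_augmentation mean number of randomly chosen
#'   unknown-status symptoms revealed as `FALSE` per training example
#'   (Poisson, resampled every batch).  At dialogue time the simulated
#'   patient denies queried symptoms absent from the record, so the
#'   classifier must be robust to denied findings it never saw in the
#'   raw records; 0 disables the augmentation.
#' @param implicit_dropout probability that each implicit symptom's
#'   status is hidden (set back to unknown) in a training example,
#'   resampled every batch.  Dialogue-time inputs reveal only the
#'   implicit symptoms the agent happened to query, so the classifier is
#'   trained on the same spectrum of partial reveals; explicit
#'   (self-report) symptoms are always visible.  0 disables.
#' @param batch_size mini-batch size.
#' @param seed integer seed; training is deterministic given the seed.
#' @return Object of class `disease_classifier` with the network, the
#'   vocabularies and `train_accuracy`.
#' @export
train_classifier <- function(dataset, hidden = 256L, epochs = 30L,
                             lr = 0.02, momentum = 0.9,
                             negative_augmentation = 3,
                             implicit_dropout = 0.5,
                             batch_size = 100L, seed = 1L) {
  stopifnot(inherits(dataset, "diag_dataset"),
            length(dataset$records) > 0L)
  if (length(unique(vapply(dataset$records, `[[`, "", "disease"))) < 2L)
    warning("dataset contains a single disease class; ",
            "classifier will be degenerate")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  v <- dataset$symptoms
  n <- length(dataset$records)
  X <- t(vapply(dataset$records,
                function(r) encode_status_onehot(record_status(r, v), v),
                numeric(3L * length(v))))
  y <- match(vapply(dataset$records, `[[`, "", "disease"),
             dataset$diseases)
  imp_idx <- lapply(dataset$records, function(r)
    match(names(r$implicit), v))
  K <- length(dataset$diseases)
  net <- mlp_new(ncol(X), as.integer(hidden), K)

  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      nv <- length(v)
      for (b in seq_along(idx)) {
        if (implicit_dropout > 0) {
          ji <- imp_idx[[idx[b]]]
          hide <- ji[stats::runif(length(ji)) < implicit_dropout]
          if (length(hide)) {
            Xb[b, 3L * (hide - 1L) + 1L] <- 0  # true off
            Xb[b, 3L * (hide - 1L) + 2L] <- 0  # false off
            Xb[b, 3L * (hide - 1L) + 3L] <- 1  # unknown on
          }
        }
        if (negative_augmentation > 0) {
          m <- stats::rpois(1L, negative_augmentation)
          if (m > 0L) {
            js <- sample.int(nv, min(m, nv))
            unk <- js[Xb[b, 3L * (js - 1L) + 3L] == 1]
            if (length(unk)) {
              Xb[b, 3L * (unk - 1L) + 3L] <- 0   # unknown off
              Xb[b, 3L * (unk - 1L) + 2L] <- 1   # false on
            }
          }
        }
      }
      fwd <- mlp_forward(net, Xb)
      P <- softmax_rows(fwd$out)
      Yb <- matrix(0, length(idx), K)
      Yb[cbind(seq_along(idx), y[idx])] <- 1
      net <- mlp_sgd(net, Xb, fwd, (P - Yb) / length(idx), lr,
                     momentum = momentum)
    }
  }
  pred <- max.col(mlp_forward(net, X)$out, ties.method = "first")
  structure(list(net = net, symptoms = v, diseases = dataset$diseases,
                 train_accuracy = mean(pred == y)),
            class = "disease_classifier")
}

#' @export
print.disease_classifier <- function(x, ...) {
  cat(sprintf(paste0("<disease_classifier> %d symptoms -> %d diseases ",
                     "(hidden %d), train accuracy %.3f\n"),
              length(x$symptoms), length(x$diseases), x$net$d_hidden,
              x$train_accuracy))
  invisible(x)
}

#' Predict the disease distribution from a symptom status
#'
#' @param model a [train_classifier()] model.
#' @param status either a named status vector over the model's symptom
#'   vocabulary (values 1 true / -1 false / 0 unknown) or an already
#'   encoded numeric vector of length `3 * |symptoms|`.
#' @return A data frame with columns `disease` and `probability`, ranked by
#'   decreasing probability (ties by disease index); probabilities sum
#'   to 1.  The first row is the diagnosis; the top-k prefix supports the
#'   disease-coverage metric.
#' @export
predict_disease <- function(model, status) {
  stopifnot(inherits(model, "disease_classifier"))
  if (is.null(names(status))) {
    if (length(status) != model$net$d_in)
      stop("encoding length ", length(status),
           " does not match classifier input ", model$net$d_in)
    enc <- as.numeric(status)
  } else {
    enc <- encode_status_onehot(status, model$symptoms)
  }
  z <- mlp_predict1(model$net, enc)
  p <- drop(softmax_rows(matrix(z, 1L)))
  ord <- order(-p, seq_along(p))
  data.frame(disease = model$diseases[ord], probability = p[ord],
             stringsAsFactors = FALSE)
}
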