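# Minimal single-hidden-layer feed-forward network (ReLU hidden, linear
# output) with plain SGD.  Shared numerical core of the Q-value networks
# and the disease classifier.  All parameters are dense base-R matrices;
# initialisation draws from the current RNG stream so callers control
# determinism with set.seed().

mlp_new <- function(d_in, d_hidden, d_out) {
  list(W1 = matrix(stats::rnorm(d_in * d_hidden, sd = sqrt(2 / d_in)),
                   d_in, d_hidden),
       b1 = numeric(d_hidden),
       W2 = matrix(stats::rnorm(d_hidden * d_out, sd = sqrt(2 / d_hidden)),
                   d_hidden, d_out),
       b2 = numeric(d_out),
       d_in = d_in, d_hidden = d_hidden, d_out = d_out)
}

# X: n x d_in matrix. Returns list(H = hidden activations, out = n x d_out).
mlp_forward <- function(net, X) {
  H <- X %*% net$W1
  H <- pmax(sweep(H, 2L, net$b1, `+`), 0)
  out <- sweep(H %*% net$W2, 2L, net$b2, `+`)
  list(H = H, out = out)
}

# single forward pass for one state vector; returns the output row
mlp_predict1 <- function(net, x) {
  h <- pmax(drop(x %*% net$W1) + net$b1, 0)
  drop(h %*% net$W2) + net$b2
}

# one SGD step given dL/dOut (n x d_out); fwd is mlp_forward(net, X).
# With momentum > 0 a classical velocity term is kept on the net.
mlp_sgd <- function(net, X, fwd, d_out, lr, momentum = 0) {
  dW2 <- crossprod(fwd$H, d_out)
  db2 <- colSums(d_out)
  dH <- tcrossprod(d_out, net$W2)
  dH[fwd$H <= 0] <- 0
  dW1 <- crossprod(X, dH)
  db1 <- colSums(dH)
  if (momentum > 0) {
    if (is.null(net$vW1)) {
      net$vW1 <- 0 * net$W1; net$vb1 <- 0 * net$b1
      net$vW2 <- 0 * net$W2; net$vb2 <- 0 * net$b2
    }
    net$vW1 <- momentum * net$vW1 - lr * dW1
    net$vb1 <- momentum * net$vb1 - lr * db1
    net$vW2 <- momentum * net$vW2 - lr * dW2
    net$vb2 <- momentum * net$vb2 - lr * db2
    net$W1 <- net$W1 + net$vW1
    net$b1 <- net$b1 + net$vb1
    net$W2 <- net$W2 + net$vW2
    net$b2 <- net$b2 + net$vb2
  } else {
    net$W1 <- net$W1 - lr * dW1
    net$b1 <- net$b1 - lr * db1
    net$W2 <- net$W2 - lr * dW2
    net$b2 <- net$b2 - lr * db2
  }
  net
}

softmax_rows <- function(M) {
  M <- M - apply(M, 1L, max)
  E <- exp(M)
  E / rowSums(E)
}
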