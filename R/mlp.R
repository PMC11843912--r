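# Minimal single-hidden-layer perceptron: 100 rectified-linear units, sigmoid
# output, binary cross-entropy, Adam updates on shuffled mini-batches.
# Implemented in-package because no installed R package offers a ReLU/Adam
# MLP; inputs are expected pre-standardized by the caller.

fit_mlp <- function(x, y, hidden = 100L, epochs = 150L, batch_size = 32L,
                    lr = 1e-3, l2 = 1e-4, seed = 1L) {
  stopifnot(is.matrix(x), length(y) == nrow(x), all(y %in% c(0, 1)))
  p <- ncol(x)
  n <- nrow(x)
  with_seed(seed, {
    w1 <- matrix(stats::rnorm(p * hidden, sd = sqrt(2 / p)), p, hidden)
    b1 <- numeric(hidden)
    w2 <- matrix(stats::rnorm(hidden, sd = sqrt(2 / hidden)), hidden, 1)
    b2 <- 0
    ms <- list(w1 = w1 * 0, b1 = b1 * 0, w2 = w2 * 0, b2 = 0)
    vs <- ms
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        xb <- x[idx, , drop = FALSE]
        yb <- y[idx]
        m <- length(idx)
        z1 <- sweep(xb %*% w1, 2, b1, "+")
        a1 <- pmax(z1, 0)
        z2 <- drop(a1 %*% w2) + b2
        prob <- 1 / (1 + exp(-z2))
        d2 <- matrix((prob - yb) / m, ncol = 1)     # d loss / d z2
        gw2 <- crossprod(a1, d2) + l2 * w2
        gb2 <- sum(d2)
        d1 <- (d2 %*% t(w2)) * (z1 > 0)
        gw1 <- crossprod(xb, d1) + l2 * w1
        gb1 <- colSums(d1)
        step <- step + 1L
        grads <- list(w1 = gw1, b1 = gb1, w2 = gw2, b2 = gb2)
        for (nm in names(grads)) {
          ms[[nm]] <- beta1 * ms[[nm]] + (1 - beta1) * grads[[nm]]
          vs[[nm]] <- beta2 * vs[[nm]] + (1 - beta2) * grads[[nm]]^2
          mhat <- ms[[nm]] / (1 - beta1^step)
          vhat <- vs[[nm]] / (1 - beta2^step)
          upd <- lr * mhat / (sqrt(vhat) + eps)
          if (nm == "w1") w1 <- w1 - upd
          else if (nm == "b1") b1 <- b1 - upd
          else if (nm == "w2") w2 <- w2 - upd
          else b2 <- b2 - upd
        }
      }
    }
    structure(list(w1 = w1, b1 = b1, w2 = w2, b2 = b2), class = "mlp_net")
  })
}

predict_mlp <- function(net, x) {
  a1 <- pmax(sweep(x %*% net$w1, 2, net$b1, "+"), 0)
  drop(1 / (1 + exp(-(a1 %*% net$w2 + net$b2))))
}
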