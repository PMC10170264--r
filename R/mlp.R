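# Feed-forward neural network for pseudovalue regression.
#
# Fully connected layers with rectified-linear hidden activations and a
# single linear output, trained with the Adam optimiser on mini-batches
# (default batch size 1024) under a root-mean-squared-error loss. The
# learning rate is halved once the epoch loss has plateaued for three
# epochs, and training stops early after five epochs without an improvement
# of at least `tol` (default 1e-4).

#' Fit a feed-forward network on a numeric design
#'
#' @param X Numeric matrix (rows = observations); for risk modelling the
#'   inputs should be min-max scaled to \[0, 1\] beforehand.
#' @param y Numeric target (pseudovalues).
#' @param hidden Integer vector of hidden-layer widths.
#' @param lr Initial learning rate (Adam).
#' @param epochs Maximum training epochs.
#' @param batch Mini-batch size.
#' @param seed Integer seed (weight initialisation and shuffling).
#' @param tol Minimum loss improvement counted as progress.
#' @param patience_lr,patience_stop Plateau epochs before halving the
#'   learning rate / stopping early.
#' @return Object of class `crp_mlp` with weight matrices and the training
#'   loss trace.
#' @export
mlp_fit <- function(X, y, hidden = c(30), lr = 0.01, epochs = 20,
                    batch = 1024, seed = 1L, tol = 1e-4,
                    patience_lr = 3L, patience_stop = 5L) {
  stopifnot(is.matrix(X), nrow(X) == length(y), all(hidden >= 1))
  set.seed(seed)
  sizes <- c(ncol(X), hidden, 1L)
  L <- length(sizes) - 1L
  W <- lapply(seq_len(L), function(l)             # He initialisation
    matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0, sqrt(2 / sizes[l])),
           sizes[l], sizes[l + 1]))
  b <- lapply(seq_len(L), function(l) numeric(sizes[l + 1]))
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; step <- 0

  n <- nrow(X); loss_trace <- numeric(0)
  best <- Inf; stall <- 0L
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    for (s in split(idx, ceiling(seq_along(idx) / batch))) {
      xb <- X[s, , drop = FALSE]; yb <- y[s]
      # forward
      a <- vector("list", L + 1L); a[[1]] <- xb
      for (l in seq_len(L)) {
        z <- sweep(a[[l]] %*% W[[l]], 2, b[[l]], "+")
        a[[l + 1]] <- if (l < L) pmax(z, 0) else z
      }
      # backward (gradient of RMSE via MSE scaling at the loss root)
      pred <- drop(a[[L + 1]])
      delta <- matrix(2 * (pred - yb) / length(yb), ncol = 1)
      step <- step + 1
      for (l in seq(L, 1)) {
        gW <- crossprod(a[[l]], delta)
        gb <- colSums(delta)
        if (l > 1) delta <- (delta %*% t(W[[l]])) * (a[[l]] > 0)
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        mhW <- mW[[l]] / (1 - beta1^step); vhW <- vW[[l]] / (1 - beta2^step)
        mhb <- mb[[l]] / (1 - beta1^step); vhb <- vb[[l]] / (1 - beta2^step)
        W[[l]] <- W[[l]] - lr * mhW / (sqrt(vhW) + eps)
        b[[l]] <- b[[l]] - lr * mhb / (sqrt(vhb) + eps)
      }
    }
    fit <- list(W = W, b = b)
    loss <- sqrt(mean((mlp_forward(fit, X) - y)^2))
    loss_trace <- c(loss_trace, loss)
    if (loss < best - tol) { best <- loss; stall <- 0L } else stall <- stall + 1L
    if (stall >= patience_stop) break
    if (stall >= patience_lr) lr <- lr / 2
  }
  structure(list(W = W, b = b, loss_trace = loss_trace, hidden = hidden),
            class = "crp_mlp")
}

mlp_forward <- function(fit, X) {
  a <- X
  L <- length(fit$W)
  for (l in seq_len(L)) {
    z <- sweep(a %*% fit$W[[l]], 2, fit$b[[l]], "+")
    a <- if (l < L) pmax(z, 0) else z
  }
  drop(a)
}

#' @export
predict.crp_mlp <- function(object, newdata, ...) mlp_forward(object, newdata)
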