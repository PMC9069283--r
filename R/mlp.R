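
# Feed-forward regression network used for the stage-wise Q-functions.
# Deliberately small: full-batch Adam with backpropagation in base matrix
# ops, ReLU hidden layers, a linear output, mean-squared-error loss. With no
# hidden layers it degenerates to a linear model trained the same way. The
# offline setting (a few hundred fixed episodes, low-dimensional states)
# makes full-batch training both adequate and exactly reproducible.

#' Fit a small feed-forward regression network
#'
#' Training is full-batch Adam; the learning rate is halved whenever the
#' loss plateaus, and training stops when the maximum absolute parameter
#' change over an epoch falls below `tol` (the weights have converged) or at
#' `max_epochs`. Fixed seeds give bit-identical fits.
#'
#' @param x Numeric matrix of inputs (rows are cases).
#' @param y Numeric response.
#' @param hidden Integer vector of hidden-layer widths; `integer(0)` or
#'   `NULL` gives a linear model.
#' @param lr Initial Adam learning rate.
#' @param max_epochs Maximum training epochs.
#' @param tol Convergence tolerance on the per-epoch parameter change.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `ot_mlp` with weights, epochs used, and final
#'   loss.
#' @export
mlp_fit <- function(x, y, hidden = c(64, 64), lr = 1e-2, max_epochs = 2000,
                    tol = 1e-4, seed = 1) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y))
  hidden <- as.integer(hidden %||% integer(0))
  if (any(hidden < 1)) abort("Hidden widths must be >= 1.")
  sizes <- c(ncol(x), hidden, 1L)
  L <- length(sizes) - 1L
  with_seed(seed, {
    W <- purrr::map(seq_len(L), ~ matrix(
      rnorm(sizes[.x] * sizes[.x + 1], sd = sqrt(2 / max(1, sizes[.x]))),
      sizes[.x], sizes[.x + 1]))
    b <- purrr::map(seq_len(L), ~ numeric(sizes[.x + 1]))
  })
  mW <- purrr::map(W, ~ .x * 0); vW <- mW
  mb <- purrr::map(b, ~ .x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  n <- nrow(x)
  best_loss <- Inf; stall <- 0L
  loss <- NA_real_; epoch <- 0L
  for (epoch in seq_len(max_epochs)) {
    # forward
    a <- vector("list", L + 1)
    a[[1]] <- x
    for (l in seq_len(L)) {
      z <- sweep(a[[l]] %*% W[[l]], 2, b[[l]], "+")
      a[[l + 1]] <- if (l < L) pmax(z, 0) else z
    }
    pred <- drop(a[[L + 1]])
    resid <- pred - y
    loss <- mean(resid^2)
    # backward
    delta <- matrix(2 * resid / n, n, 1)
    gW <- vector("list", L); gb <- vector("list", L)
    for (l in rev(seq_len(L))) {
      gW[[l]] <- crossprod(a[[l]], delta)
      gb[[l]] <- colSums(delta)
      if (l > 1) delta <- (delta %*% t(W[[l]])) * (a[[l]] > 0)
    }
    # Adam update
    t_hat <- epoch
    max_delta <- 0
    for (l in seq_len(L)) {
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
      stepW <- lr * (mW[[l]] / (1 - beta1^t_hat)) /
        (sqrt(vW[[l]] / (1 - beta2^t_hat)) + eps)
      W[[l]] <- W[[l]] - stepW
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
      stepb <- lr * (mb[[l]] / (1 - beta1^t_hat)) /
        (sqrt(vb[[l]] / (1 - beta2^t_hat)) + eps)
      b[[l]] <- b[[l]] - stepb
      max_delta <- max(max_delta, max(abs(stepW)), max(abs(stepb)))
    }
    if (!is.finite(loss)) {
      abort(sprintf(
        "Training diverged (non-finite loss) at epoch %d; lower the learning rate (%.3g).",
        epoch, lr))
    }
    if (loss < best_loss - 1e-10) {
      best_loss <- loss; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= 30L) { lr <- lr / 2; stall <- 0L }
    }
    if (max_delta < tol) break
  }
  structure(list(W = W, b = b, hidden = hidden, epochs = epoch,
                 loss = loss, lr_final = lr, input_dim = ncol(x),
                 input_names = colnames(x)),
            class = "ot_mlp")
}

#' @export
predict.ot_mlp <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != object$input_dim) {
    abort(sprintf("Expected %d input columns, got %d.", object$input_dim, ncol(x)))
  }
  L <- length(object$W)
  a <- x
  for (l in seq_len(L)) {
    z <- sweep(a %*% object$W[[l]], 2, object$b[[l]], "+")
    a <- if (l < L) pmax(z, 0) else z
  }
  drop(a)
}

n_params <- function(m) sum(purrr::map_int(m$W, length)) + sum(purrr::map_int(m$b, length))
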