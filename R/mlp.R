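# One-hidden-layer feed-forward network trained by full-batch backpropagation
# on a sum-of-squares loss, with logistic units throughout. Deliberately
# minimal: a fixed learning rate, seeded uniform init scaled by fan-in, and
# early stopping on validation accuracy. Everything downstream (relabeling
# networks, per-view experts, pool classifiers) runs on this engine, so
# determinism given a seed is a hard contract here.

#' MLP training configuration
#'
#' @param hidden_units number of hidden neurons (>= 1).
#' @param learning_rate gradient-descent step size in (0, 1].
#' @param max_epochs training budget (default 1000).
#' @param patience consecutive validation checks without improvement before
#'   stopping (default 10).
#' @param tol minimum validation-accuracy improvement that counts (default
#'   1e-4).
#' @param seed integer seed for weight initialization.
#' @return a list of class `mlp_config`.
#' @export
mlp_config <- function(hidden_units = 10L, learning_rate = 0.1,
                       max_epochs = 1000L, patience = 10L, tol = 1e-4,
                       seed = 1L) {
  stopifnot(hidden_units >= 1L, learning_rate > 0, learning_rate <= 1,
            max_epochs >= 1L, patience >= 1L, tol >= 0)
  structure(list(hidden_units = as.integer(hidden_units),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 tol = tol, seed = as.integer(seed)),
            class = "mlp_config")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

mlp_init <- function(d, h, k, seed) {
  withr::with_seed(seed, {
    W1 <- matrix(stats::runif((d + 1L) * h, -0.5, 0.5) / sqrt(d + 1L),
                 d + 1L, h)
    W2 <- matrix(stats::runif((h + 1L) * k, -0.5, 0.5) / sqrt(h + 1L),
                 h + 1L, k)
    list(W1 = W1, W2 = W2)
  })
}

# Forward pass. Returns raw (pre-logistic) output activations alongside the
# logistic outputs; evidence extraction applies softmax to the raw values.
mlp_forward <- function(net, X) {
  H <- sigmoid(cbind(1, X) %*% net$W1)
  raw <- cbind(1, H) %*% net$W2
  list(hidden = H, raw = raw, out = sigmoid(raw))
}

# Fit the network on one-hot targets Y. `val_score` (optional) maps logistic
# outputs for the validation set to an accuracy in [0, 1]; when absent,
# early stopping is disabled and the full epoch budget is used.
mlp_fit <- function(X, Y, cfg, Xval = NULL, val_score = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); d <- ncol(X); k <- ncol(Y)
  stopifnot(nrow(Y) == n)
  net <- mlp_init(d, cfg$hidden_units, k, cfg$seed)
  use_val <- !is.null(Xval) && !is.null(val_score) && NROW(Xval) > 0L
  if (!use_val && (!is.null(Xval) || !is.null(val_score)))
    warning("empty validation set: early stopping disabled")
  Xb <- cbind(1, X)
  Xvb <- if (use_val) cbind(1, as.matrix(Xval))
  best <- list(net = net, acc = -Inf, epoch = 0L)
  stale <- 0L
  lr <- cfg$learning_rate
  epoch <- 0L
  while (epoch < cfg$max_epochs) {
    epoch <- epoch + 1L
    H <- sigmoid(Xb %*% net$W1)
    Hb <- cbind(1, H)
    O <- sigmoid(Hb %*% net$W2)
    E <- O - Y
    if (!all(is.finite(E))) stop("non-finite training loss at epoch ", epoch)
    d2 <- E * O * (1 - O)
    d1 <- (d2 %*% t(net$W2[-1L, , drop = FALSE])) * H * (1 - H)
    # classic batch delta rule: gradient of the total (summed) SSE
    net$W2 <- net$W2 - lr * crossprod(Hb, d2)
    net$W1 <- net$W1 - lr * crossprod(Xb, d1)
    if (use_val) {
      Ov <- sigmoid(cbind(1, sigmoid(Xvb %*% net$W1)) %*% net$W2)
      acc <- val_score(Ov)
      if (acc > best$acc + cfg$tol) {
        best <- list(net = net, acc = acc, epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= cfg$patience) break
      }
    }
  }
  if (use_val && best$epoch > 0L) net <- best$net
  list(net = net, epochs = epoch,
       val_accuracy = if (use_val) best$acc else NA_real_,
       cfg = cfg, d = d, k = k)
}

mlp_predict_raw <- function(fit, X) mlp_forward(fit$net, as.matrix(X))$raw

mlp_predict_out <- function(fit, X) mlp_forward(fit$net, as.matrix(X))$out

#' Numerically stable softmax
#'
#' Row-wise softmax of a matrix (or a single vector) of activations;
#' invariant to adding a constant per row.
#'
#' @param a numeric vector or matrix of activations.
#' @return object of the same shape with nonnegative rows summing to 1.
#' @export
softmax <- function(a) {
  if (is.null(dim(a))) {
    e <- exp(a - max(a))
    return(e / sum(e))
  }
  e <- exp(a - apply(a, 1L, max))
  e / rowSums(e)
}
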