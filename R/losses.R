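#' Loss configuration for the ensemble objective
#'
#' The training objective is `alpha * CE + beta * logCosh`, a weighted
#' ensemble of categorical cross-entropy and the logarithm of the hyperbolic
#' cosine of the prediction error. Both component weights default to 0.5,
#' the setting that balances the probabilistic CE term against the
#' L2-small/L1-large behaviour of log-cosh.
#'
#' @param name One of `"ce"`, `"logcosh"`, `"ce_logcosh"`. Selecting `"ce"`
#'   or `"logcosh"` fixes the weights to (1, 0) or (0, 1); `"ce_logcosh"`
#'   uses `alpha`/`beta`.
#' @param alpha Non-negative weight on cross-entropy.
#' @param beta Non-negative weight on log-cosh.
#' @param epsilon Clamp applied to probabilities before logarithms.
#' @return A `loss_config` list with elements `name`, `alpha`, `beta`,
#'   `epsilon`.
#' @export
#' @examples
#' loss_config("ce_logcosh")
loss_config <- function(name = c("ce_logcosh", "ce", "logcosh"),
                        alpha = 0.5, beta = 0.5, epsilon = 1e-7) {
  name <- match.arg(name)
  if (name == "ce") {
    alpha <- 1; beta <- 0
  } else if (name == "logcosh") {
    alpha <- 0; beta <- 1
  }
  if (alpha < 0 || beta < 0) stop_input("loss weights must be non-negative")
  if (alpha + beta <= 0) {
    stop_input("invalid loss config: alpha + beta must be positive")
  }
  structure(list(name = name, alpha = alpha, beta = beta, epsilon = epsilon),
            class = "loss_config")
}

as_pred_matrix <- function(y) {
  if (is.null(dim(y))) matrix(y, nrow = 1) else as.matrix(y)
}

#' Cross-entropy loss
#'
#' Mean over the batch of `-sum_i y_i log(y_hat_i)` with probabilities
#' clamped to `[epsilon, 1 - epsilon]` before the logarithm.
#'
#' @param y True labels, one-hot; a vector for one sample or an
#'   n-samples-by-n-classes matrix.
#' @param y_hat Predicted class probabilities, same shape as `y`.
#' @param epsilon Clamp for the log argument.
#' @return A single non-negative number.
#' @export
#' @examples
#' cross_entropy(c(1, 0), c(0.5, 0.5)) # -log(0.5)
cross_entropy <- function(y, y_hat, epsilon = 1e-7) {
  y <- as_pred_matrix(y); y_hat <- as_pred_matrix(y_hat)
  stopifnot(all(dim(y) == dim(y_hat)))
  p <- clamp(y_hat, epsilon, 1 - epsilon)
  mean(rowSums(-y * log(p)))
}

#' Gradient of [cross_entropy()] with respect to the predictions.
#' @inheritParams cross_entropy
#' @return Matrix (or vector) matching `y_hat`.
#' @export
cross_entropy_grad <- function(y, y_hat, epsilon = 1e-7) {
  y <- as_pred_matrix(y); yh <- as_pred_matrix(y_hat)
  p <- clamp(yh, epsilon, 1 - epsilon)
  g <- -(y / p) * (yh > epsilon & yh < 1 - epsilon) / nrow(y)
  if (is.null(dim(y_hat))) drop(g) else g
}

# log(cosh(e)) via the overflow-safe identity
# log cosh e = |e| + log1p(exp(-2|e|)) - log 2.
log_cosh_scalar <- function(e) {
  a <- abs(e)
  a + log1p(exp(-2 * a)) - log(2)
}

#' Log-hyperbolic-cosine loss
#'
#' Sum over classes of `log(cosh(y_hat - y))`, averaged over the batch.
#' Behaves like half the squared error for small errors and like the
#' absolute error minus `log 2` for large ones, combining the smoothness
#' of L2 near the optimum with the robustness of L1 far from it.
#'
#' @inheritParams cross_entropy
#' @return A single non-negative number.
#' @export
#' @examples
#' log_cosh(c(1, 0), c(1, 0)) # 0
log_cosh <- function(y, y_hat) {
  y <- as_pred_matrix(y); y_hat <- as_pred_matrix(y_hat)
  stopifnot(all(dim(y) == dim(y_hat)))
  mean(rowSums(log_cosh_scalar(y_hat - y)))
}

#' Gradient of [log_cosh()] with respect to the predictions.
#' @inheritParams cross_entropy
#' @return Matrix (or vector) matching `y_hat`.
#' @export
log_cosh_grad <- function(y, y_hat) {
  y <- as_pred_matrix(y); yh <- as_pred_matrix(y_hat)
  g <- tanh(yh - y) / nrow(y)
  if (is.null(dim(y_hat))) drop(g) else g
}

#' Weighted CE-logCosh ensemble loss
#'
#' `alpha * cross_entropy + beta * log_cosh`, exactly linear in both
#' weights.
#'
#' @inheritParams cross_entropy
#' @param config A [loss_config()].
#' @return A single non-negative number.
#' @export
#' @examples
#' ensemble_loss(c(1, 0), c(0.5, 0.5), loss_config("ce_logcosh"))
ensemble_loss <- function(y, y_hat, config = loss_config()) {
  stopifnot(inherits(config, "loss_config"))
  config$alpha * cross_entropy(y, y_hat, config$epsilon) +
    config$beta * log_cosh(y, y_hat)
}

#' Gradient of [ensemble_loss()] with respect to the predictions.
#' @inheritParams ensemble_loss
#' @return Matrix (or vector) matching `y_hat`.
#' @export
ensemble_loss_grad <- function(y, y_hat, config = loss_config()) {
  config$alpha * cross_entropy_grad(y, y_hat, config$epsilon) +
    config$beta * log_cosh_grad(y, y_hat)
}

# Gradient of the ensemble loss with respect to softmax logits for one
# sample: chains d loss / d y_hat through the softmax Jacobian.
ensemble_logit_grad <- function(y, probs, config) {
  gy <- config$alpha * (-(y / clamp(probs, config$epsilon, 1 - config$epsilon))) +
    config$beta * tanh(probs - y)
  # J^T g with J = diag(p) - p p^T
  probs * (gy - sum(gy * probs))
}
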