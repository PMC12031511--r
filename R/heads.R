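#' Private task heads and losses
#'
#' Each institution owns its prediction layer: a logistic head
#' `y_hat = sigmoid(W_cla . s + b_cla)` for terminal mortality and a linear
#' head `y_hat = W_reg . s + b_reg` for the remaining length of stay,
#' supervised at every record of the stay. Losses are the standard
#' non-negative conventions: mean binary cross-entropy over patients and mean
#' squared error over records.
#'
#' @name heads
NULL

PROB_CLAMP <- 1e-7

#' Initialize a site's head parameters
#' @param h hidden dimension.
#' @return list `W_cla` (length h), `b_cla`, `W_reg` (length h), `b_reg`.
#' @export
init_head_params <- function(h) {
  lim <- 1 / sqrt(h)
  list(W_cla = stats::runif(h, -lim, lim), b_cla = 0,
       W_reg = stats::runif(h, -lim, lim), b_reg = 0)
}

#' Mortality probability from a health-status representation
#'
#' @param head [init_head_params()] output.
#' @param s numeric vector of length `h`, or matrix `[B x h]`.
#' @return probability (vector), clamped to `[1e-7, 1 - 1e-7]` for loss
#'   stability.
#' @export
predict_classification <- function(head, s) {
  s <- if (is.matrix(s)) s else matrix(s, nrow = 1)
  p <- sigmoid_mat(drop(s %*% head$W_cla) + head$b_cla)
  pmin(pmax(p, PROB_CLAMP), 1 - PROB_CLAMP)
}

#' Remaining length-of-stay prediction
#' @inheritParams predict_classification
#' @return numeric vector (no output nonlinearity).
#' @export
predict_regression <- function(head, s) {
  s <- if (is.matrix(s)) s else matrix(s, nrow = 1)
  drop(s %*% head$W_reg) + head$b_reg
}

#' Mean binary cross-entropy
#'
#' `-(1/S) sum [y log y_hat + (1-y) log(1-y_hat)]`; non-negative by
#' construction.
#'
#' @param y_hat predicted probabilities.
#' @param y 0/1 labels, same length.
#' @return non-negative scalar.
#' @export
bce_loss <- function(y_hat, y) {
  stopifnot(length(y_hat) == length(y), length(y) >= 1)
  -mean(y * log(y_hat) + (1 - y) * log(1 - y_hat))
}

#' Mean squared error (and rmse / mae helpers)
#' @param y_hat predictions.
#' @param y targets, same length.
#' @return non-negative scalar.
#' @export
mse_loss <- function(y_hat, y) {
  stopifnot(length(y_hat) == length(y), length(y) >= 1)
  mean((y - y_hat)^2)
}

#' @rdname mse_loss
#' @export
rmse_loss <- function(y_hat, y) sqrt(mse_loss(y_hat, y))

#' @rdname mse_loss
#' @export
mae_loss <- function(y_hat, y) {
  stopifnot(length(y_hat) == length(y), length(y) >= 1)
  mean(abs(y - y_hat))
}
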