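# Gated recurrent unit channel, input dimension 1, batched across patients.
#
# Gate equations (documented convention; the independent scalar oracle in the
# test suite re-implements exactly these):
#   z_t  = sigmoid(Wz x_t + Uz h_{t-1} + bz)        update gate
#   r_t  = sigmoid(Wr x_t + Ur h_{t-1} + br)        reset gate
#   c_t  = tanh  (Wh x_t + Uh (r_t * h_{t-1}) + bh) candidate
#   h_t  = (1 - z_t) * h_{t-1} + z_t * c_t
# h_0 = 0. With all weights and biases zero, h stays exactly 0.
# Wz/Wr/Wh are length-h vectors because the channel input is a scalar.

#' Initialize parameters of one per-feature recurrent channel
#'
#' Uniform(-1/sqrt(h), 1/sqrt(h)) initialization, drawn from the current RNG
#' stream; callers seed the stream so that shared channels start identical at
#' every site.
#'
#' @param h hidden dimension.
#' @return list of class `gru_params` with gates `Wz, Wr, Wh` (length-`h`
#'   input weights), `Uz, Ur, Uh` (`h x h` recurrent weights), `bz, br, bh`.
#' @export
init_gru_params <- function(h) {
  lim <- 1 / sqrt(h)
  u <- function(n) stats::runif(n, -lim, lim)
  structure(list(
    Wz = u(h), Wr = u(h), Wh = u(h),
    Uz = matrix(u(h * h), h, h), Ur = matrix(u(h * h), h, h),
    Uh = matrix(u(h * h), h, h),
    bz = u(h), br = u(h), bh = u(h)), class = "gru_params")
}

sigmoid_mat <- function(x) 1 / (1 + exp(-x))

# Forward pass over a padded batch.
#   X: [B x Tmax] scalar inputs (padding values are ignored);
#   L: integer lengths, 1 <= L_b <= Tmax.
# Returns H: list of Tmax+1 matrices [B x h] (H[[1]] is the zero initial
# state; H[[t+1]] the state after consuming x_t), plus gate caches for
# backprop. Rows past a sequence's length carry the last real state forward.
gru_forward <- function(params, X, L) {
  B <- nrow(X); Tmax <- ncol(X); h <- length(params$bz)
  H <- vector("list", Tmax + 1)
  Z <- R <- C <- vector("list", Tmax)
  H[[1]] <- matrix(0, B, h)
  bz <- matrix(params$bz, B, h, byrow = TRUE)
  br <- matrix(params$br, B, h, byrow = TRUE)
  bh <- matrix(params$bh, B, h, byrow = TRUE)
  for (t in seq_len(Tmax)) {
    Hp <- H[[t]]
    x <- X[, t]
    Zt <- sigmoid_mat(outer(x, params$Wz) + tcrossprod(Hp, params$Uz) + bz)
    Rt <- sigmoid_mat(outer(x, params$Wr) + tcrossprod(Hp, params$Ur) + br)
    Ct <- tanh(outer(x, params$Wh) + tcrossprod(Rt * Hp, params$Uh) + bh)
    Hn <- (1 - Zt) * Hp + Zt * Ct
    inactive <- L < t
    if (any(inactive)) Hn[inactive, ] <- Hp[inactive, , drop = FALSE]
    H[[t + 1]] <- Hn
    Z[[t]] <- Zt; R[[t]] <- Rt; C[[t]] <- Ct
  }
  list(H = H, Z = Z, R = R, C = C, X = X, L = L)
}

# Backpropagation through time.
#   fwd:    output of gru_forward.
#   dH_out: list of Tmax matrices [B x h]; dH_out[[t]] is the downstream
#           gradient on the state after step t (NULL entries mean zero).
# Returns gradients keyed like the parameter list.
gru_backward <- function(params, fwd, dH_out) {
  X <- fwd$X; L <- fwd$L
  B <- nrow(X); Tmax <- ncol(X); h <- length(params$bz)
  g <- list(Wz = numeric(h), Wr = numeric(h), Wh = numeric(h),
            Uz = matrix(0, h, h), Ur = matrix(0, h, h), Uh = matrix(0, h, h),
            bz = numeric(h), br = numeric(h), bh = numeric(h))
  dh <- matrix(0, B, h)
  for (t in rev(seq_len(Tmax))) {
    if (!is.null(dH_out[[t]])) dh <- dh + dH_out[[t]]
    act <- as.numeric(L >= t)
    Hp <- fwd$H[[t]]; Zt <- fwd$Z[[t]]; Rt <- fwd$R[[t]]; Ct <- fwd$C[[t]]
    x <- X[, t]
    dh_act <- dh * act
    dz <- dh_act * (Ct - Hp)
    dc <- dh_act * Zt
    dhp <- dh_act * (1 - Zt) + dh * (1 - act)  # inactive rows pass through
    da_c <- dc * (1 - Ct^2)
    g$Wh <- g$Wh + colSums(da_c * x)
    g$Uh <- g$Uh + crossprod(da_c, Rt * Hp)
    g$bh <- g$bh + colSums(da_c)
    dRH <- da_c %*% params$Uh
    dr <- dRH * Hp
    dhp <- dhp + dRH * Rt
    da_z <- dz * Zt * (1 - Zt)
    g$Wz <- g$Wz + colSums(da_z * x)
    g$Uz <- g$Uz + crossprod(da_z, Hp)
    g$bz <- g$bz + colSums(da_z)
    dhp <- dhp + da_z %*% params$Uz
    da_r <- dr * Rt * (1 - Rt)
    g$Wr <- g$Wr + colSums(da_r * x)
    g$Ur <- g$Ur + crossprod(da_r, Hp)
    g$br <- g$br + colSums(da_r)
    dhp <- dhp + da_r %*% params$Ur
    dh <- dhp
  }
  g
}
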