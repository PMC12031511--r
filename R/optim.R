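# Adam / AdamW on flat keyed parameter lists. Per-key step counts, so a key
# that is frozen in some rounds (a feature another site does not record) keeps
# correct bias correction for the steps it does take.

#' Initialize optimizer state for a flat parameter list
#' @param params named list of numeric arrays.
#' @return opaque state list.
#' @export
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = stats::setNames(rep(0, length(params)), names(params)))
}

#' One Adam / AdamW step on the keys present in `grads`
#'
#' AdamW applies decoupled weight decay (`p <- p - lr * wd * p`) before the
#' adaptive update; plain Adam ignores `weight_decay`. Keys absent from
#' `grads` are left untouched (freeze-and-mask).
#'
#' @param params flat named list of arrays.
#' @param grads flat named list, keys a subset of `names(params)`.
#' @param state from [adam_init()].
#' @param lr learning rate.
#' @param beta1,beta2,eps Adam moment/stability constants.
#' @param weight_decay decoupled decay coefficient (AdamW only).
#' @param variant `"adamw"` or `"adam"`.
#' @return list(params, state).
#' @export
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0.01,
                      variant = c("adamw", "adam")) {
  variant <- match.arg(variant)
  for (key in names(grads)) {
    g <- grads[[key]]
    if (is.null(state$m[[key]])) {
      state$m[[key]] <- g * 0
      state$v[[key]] <- g * 0
      state$t[key] <- 0
    }
    state$t[key] <- state$t[key] + 1
    tk <- state$t[[key]]
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
    mhat <- state$m[[key]] / (1 - beta1^tk)
    vhat <- state$v[[key]] / (1 - beta2^tk)
    p <- params[[key]]
    if (variant == "adamw" && weight_decay > 0) p <- p - lr * weight_decay * p
    params[[key]] <- p - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
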