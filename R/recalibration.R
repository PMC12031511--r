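#' Attention-based feature recalibration
#'
#' Each canonical feature row `f_i` of the per-patient matrix `F` owns a
#' private triple of square projection matrices producing a query from the
#' patient context, and a key and value from the row itself:
#' `q_i = W_i^q f_bar`, `k_i = W_i^k f_i`, `v_i = W_i^v f_i`. The context
#' `f_bar` is the mean of the recorded rows (including the demographic row).
#' Raw scores `zeta_i = q_i . k_i` are replaced by a large negative constant
#' (`-1e9`) for rows the institution does not record, so after the softmax
#' their attention weight vanishes and the remaining weights renormalize as if
#' the rows were absent. The health-status representation is the
#' attention-weighted sum `s = sum_i alpha_i v_i`. Recalibration parameters
#' are always private to a site: they encode which features matter for *its*
#' task and are never federated.
#'
#' @name recalibration
NULL

#' Score assigned to unrecorded feature rows before the softmax
#' @export
MASK_VALUE <- -1e9

#' Initialize per-row query/key/value projections
#'
#' @param rows canonical row names (dynamic features + demographic row).
#' @param h hidden dimension.
#' @return named list: per row, `list(Wq, Wk, Wv)`, each `h x h`, drawn
#'   Uniform(-1/sqrt(h), 1/sqrt(h)) from the current RNG stream.
#' @export
init_recalibration_params <- function(rows, h) {
  lim <- 1 / sqrt(h)
  out <- lapply(rows, function(r)
    list(Wq = matrix(stats::runif(h * h, -lim, lim), h, h),
         Wk = matrix(stats::runif(h * h, -lim, lim), h, h),
         Wv = matrix(stats::runif(h * h, -lim, lim), h, h)))
  names(out) <- rows
  out
}

#' Patient context vector
#'
#' The mean of the recorded rows of `F` (unrecorded placeholder rows are
#' excluded; the demographic row is always recorded).
#'
#' @param fm a `feature_matrix` from [build_feature_matrix()], or a plain list
#'   with elements `F` and `recorded_row_mask`.
#' @return numeric vector of length `h`.
#' @export
compute_context <- function(fm) {
  rec <- which(fm$recorded_row_mask)
  if (length(rec) == 0) stop("no recorded rows: context is undefined")
  colMeans(fm$F[rec, , drop = FALSE])
}

#' Masked attention scores and weights
#'
#' @param params [init_recalibration_params()] output.
#' @param fm a `feature_matrix`.
#' @param f_bar context vector from [compute_context()].
#' @return list with `zeta` (raw scores; `MASK_VALUE` on unrecorded rows) and
#'   `alpha` (softmax weights, computed with max-subtraction stability).
#' @export
attention_scores <- function(params, fm, f_bar) {
  rows <- rownames(fm$F)
  zeta <- stats::setNames(rep(MASK_VALUE, length(rows)), rows)
  for (i in which(fm$recorded_row_mask)) {
    p <- params[[rows[i]]]
    q <- drop(p$Wq %*% f_bar)
    k <- drop(p$Wk %*% fm$F[i, ])
    zeta[i] <- sum(q * k)
  }
  e <- exp(zeta - max(zeta))
  list(zeta = zeta, alpha = e / sum(e))
}

#' Recalibrated health-status representation
#'
#' `s = sum_i alpha_i * (W_i^v f_i)` over all canonical rows; unrecorded rows
#' have zero placeholder embeddings and vanishing weights, so they contribute
#' exactly zero.
#'
#' @param alpha attention weights from [attention_scores()].
#' @param params recalibration parameters.
#' @param fm a `feature_matrix`.
#' @return numeric vector of length `h`.
#' @export
recalibrate <- function(alpha, params, fm) {
  rows <- rownames(fm$F)
  h <- ncol(fm$F)
  s <- numeric(h)
  for (i in seq_along(rows)) {
    if (alpha[i] == 0) next
    v <- drop(params[[rows[i]]]$Wv %*% fm$F[i, ])
    s <- s + alpha[i] * v
  }
  s
}

#' Export per-patient attention weights
#'
#' Writes the interpretability CSV `patient_id, feature, weight` with one row
#' per (patient, canonical feature row).
#'
#' @param weights matrix `[n_patients x n_rows]` of attention weights with
#'   rownames patient ids and colnames canonical rows.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_attention_weights <- function(weights, path) {
  df <- data.frame(
    patient_id = rep(rownames(weights), times = ncol(weights)),
    feature = rep(colnames(weights), each = nrow(weights)),
    weight = as.vector(weights))
  df <- df[order(df$patient_id, df$feature), ]
  write_csv_plain(df, path)
  invisible(path)
}
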