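#' Multi-channel sequential embedding
#'
#' Every dynamic clinical feature is embedded by its *own* recurrent channel
#' (input dimension 1, shared hidden size `h`): the channel consumes the
#' feature's standardized, imputed scalar sequence and its final hidden state
#' is the feature's embedding row. Demographics are mapped into the same
#' hidden space by a learnable linear embedding. Stacking the rows in the
#' canonical federation-wide feature order (plus one demographic row) yields
#' the per-patient feature matrix `F`; rows for features the institution does
#' not record are zero placeholders flagged by `recorded_row_mask`, so all
#' institutions share a single row indexing.
#'
#' @name encoder
NULL

#' Embed one feature's scalar sequence
#'
#' Runs the feature's recurrent channel over the sequence (initial hidden
#' state zero) and returns the final hidden state.
#'
#' @param channel a [init_gru_params()] parameter list.
#' @param series numeric vector, the standardized + imputed values over time.
#' @param obs logical vector, same length: the observation mask. The channel
#'   input is the value only; the mask is consumed downstream by the
#'   recalibration layer, but its length is validated here.
#' @return numeric vector of length `h`.
#' @export
embed_feature_sequence <- function(channel, series, obs = NULL) {
  if (length(series) < 1) stop("series must have at least one time step")
  if (!is.null(obs) && length(obs) != length(series))
    stop("series and obs must have equal length")
  fwd <- gru_forward(channel, matrix(series, nrow = 1), length(series))
  drop(fwd$H[[length(series) + 1]])
}

#' Embed demographics into the channel hidden space
#'
#' The linear map `f = W_base %*% base`. `W_base` is stored `h x m` so the
#' output lives in the `h`-dimensional hidden space of the dynamic channels.
#'
#' @param W_base `h x m` embedding matrix.
#' @param base numeric vector of length `m` (e.g. standardized age, gender code).
#' @return numeric vector of length `h`.
#' @export
embed_demographics <- function(W_base, base) {
  if (ncol(W_base) != length(base))
    stop("W_base has ", ncol(W_base), " columns but base has length ",
         length(base))
  drop(W_base %*% base)
}

#' Gaussian-error linear unit
#' @param x numeric.
#' @return `x * pnorm(x)`.
#' @export
gelu <- function(x) x * stats::pnorm(x)

gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

DEMOGRAPHIC_ROW <- "_demographics"

#' Canonical attention row names: all dynamic features plus the demographic row
#' @param manifest a [feature_manifest()].
#' @return character vector of length x+1.
#' @export
canonical_rows <- function(manifest) {
  c(canonical_dynamic_features(manifest), DEMOGRAPHIC_ROW)
}

#' Build the per-patient feature matrix F
#'
#' Stacks the recurrent embedding of every *canonical* dynamic feature (zero
#' placeholder rows, with `recorded_row_mask = FALSE`, for features this
#' institution does not record) and appends the demographic row, which passes
#' through a GELU activation in the full model. Rows are tagged `shared` or
#' `private` according to whether the feature is recorded by at least two
#' institutions in the manifest.
#'
#' @param site_model a site model from [init_site_model()] (provides channel
#'   parameters and `W_base`).
#' @param record a [patient_record()] with standardized, imputed dynamics.
#' @param manifest the federation [feature_manifest()].
#' @param demographics_transform function applied to raw demographics before
#'   embedding (default: identity; the training pipeline standardizes age).
#' @return object of class `feature_matrix`: `F` (`(x+1) x h`),
#'   `recorded_row_mask`, `partition` (per-row `"shared"`/`"private"`).
#' @export
build_feature_matrix <- function(site_model, record, manifest,
                                 demographics_transform = identity) {
  rows <- canonical_rows(manifest)
  h <- nrow(site_model$W_base)
  F_mat <- matrix(0, length(rows), h, dimnames = list(rows, NULL))
  mask <- stats::setNames(rep(FALSE, length(rows)), rows)
  shared <- shared_features(manifest)
  partition <- stats::setNames(
    ifelse(rows %in% shared, "shared", "private"), rows)
  partition[DEMOGRAPHIC_ROW] <- "shared"
  for (f in rownames(record$dynamics)) {
    F_mat[f, ] <- embed_feature_sequence(
      site_model$channels[[f]], record$dynamics[f, ], record$observed_mask[f, ])
    mask[f] <- TRUE
  }
  base <- demographics_transform(record$demographics)
  F_mat[DEMOGRAPHIC_ROW, ] <- gelu(embed_demographics(site_model$W_base, base))
  mask[DEMOGRAPHIC_ROW] <- TRUE
  structure(list(F = F_mat, recorded_row_mask = mask, partition = partition),
            class = "feature_matrix")
}
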