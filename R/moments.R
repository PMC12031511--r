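#' Privacy-pattern standardization via moment sharing
#'
#' Institutions never exchange raw values. For each feature every site computes
#' the sufficient statistics (count, sum, sum of squares) over its *observed*
#' entries; the triples are pooled with a count-weighted merge and finalized
#' into a mean and a population (divide-by-N) standard deviation, which makes
#' merging exact regardless of how values are partitioned across sites. The
#' resulting metadata drives a unified z-score standardization at every site.
#'
#' @param dataset an [institution_dataset()].
#' @param features feature names, a subset of the institution's recorded
#'   dynamic features.
#' @return named list per feature: `list(count, sum, sumsq)` over observed
#'   entries only.
#' @export
compute_local_moments <- function(dataset, features = dataset$dynamic_features) {
  bad <- setdiff(features, dataset$dynamic_features)
  if (length(bad))
    stop("feature(s) not recorded by institution '", dataset$institution_id,
         "': ", paste(bad, collapse = ", "))
  out <- vector("list", length(features))
  names(out) <- features
  for (f in features) {
    vals <- unlist(lapply(dataset$records, function(r)
      r$dynamics[f, r$observed_mask[f, ]]), use.names = FALSE)
    vals <- vals[!is.na(vals)]
    out[[f]] <- list(count = length(vals), sum = sum(vals), sumsq = sum(vals^2))
  }
  out
}

#' Merge per-site moment triples into standardization metadata
#'
#' @param moment_sets list of outputs of [compute_local_moments()]; all sets
#'   must cover the same feature list.
#' @param eps std floor: a pooled standard deviation below `eps` (or a zero
#'   pooled count) marks the feature degenerate, and [standardize()] passes its
#'   values through unchanged.
#' @return object of class `standardization_metadata`: per feature `count`,
#'   `mean`, `std` (population convention) and `degenerate`.
#' @export
merge_moments <- function(moment_sets, eps = 1e-8) {
  stopifnot(length(moment_sets) >= 1)
  feats <- names(moment_sets[[1]])
  for (ms in moment_sets) {
    if (!setequal(names(ms), feats))
      stop("all moment sets must cover the same feature list")
  }
  out <- vector("list", length(feats))
  names(out) <- feats
  for (f in feats) {
    count <- sum(vapply(moment_sets, function(ms) ms[[f]]$count, numeric(1)))
    s <- sum(vapply(moment_sets, function(ms) ms[[f]]$sum, numeric(1)))
    ss <- sum(vapply(moment_sets, function(ms) ms[[f]]$sumsq, numeric(1)))
    if (count == 0) {
      out[[f]] <- list(count = 0, mean = NA_real_, std = NA_real_,
                       degenerate = TRUE)
    } else {
      m <- s / count
      v <- max(ss / count - m^2, 0)  # clip tiny negative from cancellation
      std <- sqrt(v)
      out[[f]] <- list(count = count, mean = m, std = std,
                       degenerate = std < eps)
    }
  }
  structure(out, class = "standardization_metadata")
}

#' Apply unified z-score standardization
#'
#' Observed values become `(v - mean) / std` under the supplied metadata;
#' unobserved cells stay `NA`/masked. Degenerate features (zero pooled count or
#' near-zero std) pass through unchanged.
#'
#' @param dataset an [institution_dataset()].
#' @param metadata a `standardization_metadata` covering (at least) every
#'   recorded dynamic feature; shared features use federation-pooled metadata,
#'   private features their local moments.
#' @return the standardized dataset (`standardized = TRUE`).
#' @export
standardize <- function(dataset, metadata) {
  missing_md <- setdiff(dataset$dynamic_features, names(metadata))
  if (length(missing_md))
    stop("metadata missing for feature(s): ", paste(missing_md, collapse = ", "))
  for (i in seq_along(dataset$records)) {
    r <- dataset$records[[i]]
    for (f in dataset$dynamic_features) {
      md <- metadata[[f]]
      if (isTRUE(md$degenerate)) next
      obs <- r$observed_mask[f, ]
      r$dynamics[f, obs] <- (r$dynamics[f, obs] - md$mean) / md$std
    }
    dataset$records[[i]] <- r
  }
  dataset$standardized <- TRUE
  dataset
}

#' Mean/mode imputation after standardization
#'
#' Continuous dynamic features are mean-imputed, which in standardized space
#' fills 0; the `observed_mask` still records the original missingness because
#' the recalibration layer consumes it downstream. Missing demographics are
#' filled from `demographic_fill` (mode for categorical codes, mean for
#' continuous covariates — see [compute_demographic_fill()]).
#'
#' @param dataset a standardized [institution_dataset()].
#' @param demographic_fill optional named list of fill values per static
#'   feature, typically from [compute_demographic_fill()] on the training split.
#' @return the imputed dataset; masks are unchanged.
#' @export
impute <- function(dataset, demographic_fill = NULL) {
  if (!isTRUE(dataset$standardized))
    stop("impute() expects a standardized dataset (mean imputation fills 0 in standardized space)")
  for (i in seq_along(dataset$records)) {
    r <- dataset$records[[i]]
    r$dynamics[!r$observed_mask] <- 0
    r$dynamics[is.na(r$dynamics)] <- 0
    if (!is.null(demographic_fill)) {
      for (sf in names(demographic_fill)) {
        if (sf %in% names(r$demographics) && is.na(r$demographics[[sf]]))
          r$demographics[[sf]] <- demographic_fill[[sf]]
      }
    }
    dataset$records[[i]] <- r
  }
  dataset
}

#' Training-split fill values for demographics
#'
#' Mode for integer-coded categorical features (few distinct values), mean for
#' continuous ones.
#'
#' @param dataset an [institution_dataset()] (training split).
#' @param categorical names of static features to treat as categorical; by
#'   default those with at most 10 distinct observed values.
#' @return named list of fill values.
#' @export
compute_demographic_fill <- function(dataset, categorical = NULL) {
  out <- list()
  for (sf in dataset$static_features) {
    vals <- vapply(dataset$records, function(r) r$demographics[[sf]], numeric(1))
    vals <- vals[!is.na(vals)]
    if (!length(vals)) { out[[sf]] <- 0; next }
    is_cat <- if (is.null(categorical)) length(unique(vals)) <= 10
              else sf %in% categorical
    out[[sf]] <- if (is_cat) {
      tab <- table(vals)
      as.numeric(names(tab)[which.max(tab)])
    } else mean(vals)
  }
  out
}

#' Write/read the moments exchange file
#'
#' `moments.json` is the only artifact a site sends for standardization:
#' per-feature `{count, sum, sumsq}` triples, never raw values.
#'
#' @param moments output of [compute_local_moments()].
#' @param path file path.
#' @return `path` invisibly / the moments list.
#' @export
write_moments <- function(moments, path) {
  jsonlite::write_json(moments, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_moments
#' @export
read_moments <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(m)
    list(count = as.numeric(m$count), sum = as.numeric(m$sum),
         sumsq = as.numeric(m$sumsq)))
}
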