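#' Feature manifests for a federation of institutions
#'
#' A feature manifest records the universe of clinical feature names, the kind
#' of each feature (`"dynamic_numeric"` for longitudinal labs/vitals,
#' `"static_demographic"` for baseline covariates such as age and gender), and
#' which subset of features each institution actually records. The canonical
#' feature order is the sorted union across institutions; every per-patient
#' matrix and every parameter namespace in the package indexes features in this
#' order, so that institutions with different recorded subsets still share one
#' row indexing.
#'
#' @param recorded_by named list, one entry per institution id, each a character
#'   vector of recorded feature names (dynamic and static together).
#' @param kinds named character vector mapping every feature name appearing in
#'   `recorded_by` to `"dynamic_numeric"` or `"static_demographic"`.
#' @return An object of class `feature_manifest` with elements `feature_names`
#'   (canonical sorted union), `feature_kind` (named character), `recorded_by`.
#' @examples
#' m <- feature_manifest(
#'   recorded_by = list(A = c("age", "crp", "urea"), B = c("age", "crp")),
#'   kinds = c(age = "static_demographic", crp = "dynamic_numeric",
#'             urea = "dynamic_numeric"))
#' shared_features(m)
#' @export
feature_manifest <- function(recorded_by, kinds) {
  stopifnot(is.list(recorded_by), length(recorded_by) >= 1)
  if (is.null(names(recorded_by)) || any(names(recorded_by) == ""))
    stop("every institution in `recorded_by` must be named")
  for (inst in names(recorded_by)) {
    if (length(recorded_by[[inst]]) == 0)
      stop("institution '", inst, "' records no features; every recorded set must be non-empty")
  }
  all_feats <- sort(unique(unlist(recorded_by)))
  missing_kind <- setdiff(all_feats, names(kinds))
  if (length(missing_kind))
    stop("no kind declared for feature(s): ", paste(missing_kind, collapse = ", "))
  bad <- setdiff(unique(kinds[all_feats]), c("dynamic_numeric", "static_demographic"))
  if (length(bad))
    stop("unknown feature kind(s): ", paste(bad, collapse = ", "))
  structure(
    list(feature_names = all_feats,
         feature_kind = kinds[all_feats],
         recorded_by = lapply(recorded_by, function(f) sort(unique(f)))),
    class = "feature_manifest")
}

#' @export
print.feature_manifest <- function(x, ...) {
  cat("<feature_manifest> ", length(x$feature_names), " features, ",
      length(x$recorded_by), " institutions\n", sep = "")
  cat("  shared (>=2 sites):", length(shared_features(x)), "\n")
  invisible(x)
}

#' Features recorded by at least two institutions
#'
#' These are the features whose embedding channels are trained collaboratively;
#' a feature recorded by a single institution stays private to it.
#'
#' @param manifest a [feature_manifest()].
#' @param kind optionally restrict to one feature kind.
#' @return character vector in canonical order.
#' @export
shared_features <- function(manifest, kind = NULL) {
  counts <- feature_site_counts(manifest)
  out <- names(counts)[counts >= 2]
  if (!is.null(kind)) out <- out[manifest$feature_kind[out] == kind]
  out
}

#' Features private to one institution
#'
#' @param manifest a [feature_manifest()].
#' @param institution_id institution whose private features are wanted.
#' @return character vector of features recorded only by this institution.
#' @export
private_features <- function(manifest, institution_id) {
  counts <- feature_site_counts(manifest)
  mine <- manifest$recorded_by[[institution_id]]
  if (is.null(mine)) stop("unknown institution: ", institution_id)
  mine[counts[mine] == 1]
}

#' Pairwise shared feature set
#'
#' @param manifest a [feature_manifest()].
#' @param i,j institution ids.
#' @return character vector `recorded_by[[i]]` intersect `recorded_by[[j]]`.
#' @export
pairwise_shared <- function(manifest, i, j) {
  intersect(manifest$recorded_by[[i]], manifest$recorded_by[[j]])
}

feature_site_counts <- function(manifest) {
  tab <- table(unlist(manifest$recorded_by))
  counts <- stats::setNames(integer(length(manifest$feature_names)), manifest$feature_names)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Dynamic features of one institution, in canonical order
#' @param manifest a [feature_manifest()].
#' @param institution_id institution id.
#' @return character vector.
#' @export
institution_dynamic_features <- function(manifest, institution_id) {
  f <- manifest$recorded_by[[institution_id]]
  if (is.null(f)) stop("unknown institution: ", institution_id)
  dyn <- manifest$feature_names[manifest$feature_kind == "dynamic_numeric"]
  dyn[dyn %in% f]
}

#' Static (demographic) features of one institution, in canonical order
#' @inheritParams institution_dynamic_features
#' @return character vector.
#' @export
institution_static_features <- function(manifest, institution_id) {
  f <- manifest$recorded_by[[institution_id]]
  if (is.null(f)) stop("unknown institution: ", institution_id)
  st <- manifest$feature_names[manifest$feature_kind == "static_demographic"]
  st[st %in% f]
}

#' Canonical dynamic feature order across the federation
#' @param manifest a [feature_manifest()].
#' @return character vector (sorted union of all dynamic features).
#' @export
canonical_dynamic_features <- function(manifest) {
  manifest$feature_names[manifest$feature_kind == "dynamic_numeric"]
}
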