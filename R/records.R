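#' Patient records and institution datasets
#'
#' A `patient_record` holds one patient's dynamic feature-by-time matrix in the
#' institution's recorded feature order, a same-shape logical `observed_mask`
#' (`FALSE` where no value was recorded at that time step), a named demographics
#' vector, and task labels: a terminal binary `mortality` label and/or a
#' per-record `los_remaining` vector giving the remaining days to outcome at
#' each time index. Time is a 0-based integer record index; real-time gaps are
#' not modelled.
#'
#' @param patient_id character scalar.
#' @param dynamics numeric matrix `[n_features x T]`, rownames = feature names.
#'   Cells may be `NA` where unobserved.
#' @param observed_mask logical matrix, same shape as `dynamics`.
#' @param demographics named numeric vector of static covariates.
#' @param mortality 0/1 scalar or `NA` if the site does not label mortality.
#' @param los_remaining numeric vector of length `T` (remaining days at each
#'   record) or `NULL` for classification-only sites.
#' @return object of class `patient_record`.
#' @export
patient_record <- function(patient_id, dynamics, observed_mask, demographics,
                           mortality = NA_real_, los_remaining = NULL) {
  stopifnot(is.matrix(dynamics), is.matrix(observed_mask),
            all(dim(dynamics) == dim(observed_mask)))
  if (ncol(dynamics) < 1) stop("a patient record needs at least one time step")
  if (!is.null(los_remaining)) {
    stopifnot(length(los_remaining) == ncol(dynamics))
    if (any(los_remaining < 0, na.rm = TRUE))
      stop("los_remaining must be non-negative")
  }
  structure(
    list(patient_id = as.character(patient_id),
         dynamics = dynamics,
         observed_mask = observed_mask,
         demographics = demographics,
         mortality = mortality,
         los_remaining = los_remaining),
    class = "patient_record")
}

#' Bundle patient records into an institution dataset
#'
#' @param institution_id character scalar.
#' @param task one of `"mortality"`, `"los"`, `"both"`.
#' @param dynamic_features recorded dynamic feature names, canonical order.
#' @param static_features recorded static feature names, canonical order.
#' @param records list of [patient_record()] objects.
#' @param standardized logical, whether [standardize()] has been applied.
#' @return object of class `institution_dataset`; `n_patients(x)` gives the
#'   sample count used as the FedAvg weight.
#' @export
institution_dataset <- function(institution_id, task, dynamic_features,
                                static_features, records,
                                standardized = FALSE) {
  task <- match.arg(task, c("mortality", "los", "both"))
  for (r in records) {
    if (!identical(rownames(r$dynamics), dynamic_features))
      stop("record ", r$patient_id,
           " does not conform to the institution's dynamic feature set")
    if (!identical(names(r$demographics), static_features))
      stop("record ", r$patient_id,
           " does not conform to the institution's static feature set")
  }
  structure(
    list(institution_id = as.character(institution_id),
         task = task,
         dynamic_features = dynamic_features,
         static_features = static_features,
         records = records,
         standardized = standardized),
    class = "institution_dataset")
}

#' Number of patients in a dataset (the FedAvg weight M_n)
#' @param dataset an `institution_dataset`.
#' @return integer.
#' @export
n_patients <- function(dataset) length(dataset$records)

#' @export
print.institution_dataset <- function(x, ...) {
  cat("<institution_dataset> '", x$institution_id, "': ", n_patients(x),
      " patients, ", length(x$dynamic_features), " dynamic + ",
      length(x$static_features), " static features, task=", x$task,
      if (x$standardized) ", standardized" else "", "\n", sep = "")
  invisible(x)
}

#' Write an institution dataset directory
#'
#' Serializes a dataset to the on-disk exchange format: `manifest.json`
#' (institution id, task, feature list with kinds), `timeseries.csv`
#' (long format `patient_id,time_index,feature,value`; unobserved cells are
#' simply absent), `demographics.csv` (one column per static feature) and
#' `labels.csv` (`patient_id,time_index,mortality,los_remaining`, mortality
#' repeated on every row, `los_remaining` empty for classification-only sites).
#' CSV dialect: UTF-8, comma separator, header row, '.' decimal, empty field =
#' missing.
#'
#' @param dataset an [institution_dataset()].
#' @param path directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_institution_dataset <- function(dataset, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    institution_id = dataset$institution_id,
    task = dataset$task,
    standardized = dataset$standardized,
    features = c(
      lapply(dataset$dynamic_features,
             function(f) list(name = f, kind = "dynamic_numeric")),
      lapply(dataset$static_features,
             function(f) list(name = f, kind = "static_demographic"))))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  ts_rows <- lapply(dataset$records, function(r) {
    obs <- which(r$observed_mask, arr.ind = TRUE)
    if (nrow(obs) == 0) return(NULL)
    o <- order(obs[, 2], obs[, 1])  # by time, then feature
    obs <- obs[o, , drop = FALSE]
    data.frame(patient_id = r$patient_id,
               time_index = obs[, 2] - 1L,
               feature = rownames(r$dynamics)[obs[, 1]],
               value = r$dynamics[obs],
               stringsAsFactors = FALSE)
  })
  ts <- do.call(rbind, c(ts_rows, list(
    data.frame(patient_id = character(), time_index = integer(),
               feature = character(), value = numeric()))))
  write_csv_plain(ts, file.path(path, "timeseries.csv"))

  demo <- do.call(rbind, lapply(dataset$records, function(r)
    data.frame(patient_id = r$patient_id, t(r$demographics),
               stringsAsFactors = FALSE, check.names = FALSE)))
  if (is.null(demo))
    demo <- stats::setNames(
      data.frame(matrix(nrow = 0, ncol = 1 + length(dataset$static_features))),
      c("patient_id", dataset$static_features))
  write_csv_plain(demo, file.path(path, "demographics.csv"))

  lab_rows <- lapply(dataset$records, function(r) {
    T_len <- ncol(r$dynamics)
    data.frame(patient_id = r$patient_id,
               time_index = seq_len(T_len) - 1L,
               mortality = rep(r$mortality, T_len),
               los_remaining = if (is.null(r$los_remaining))
                 rep(NA_real_, T_len) else r$los_remaining,
               stringsAsFactors = FALSE)
  })
  write_csv_plain(do.call(rbind, lab_rows), file.path(path, "labels.csv"))
  invisible(path)
}

write_csv_plain <- function(df, file) {
  utils::write.csv(df, file, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
}

#' Load an institution dataset directory
#'
#' Reads the format written by [write_institution_dataset()]. Cells absent from
#' `timeseries.csv` (or present with an empty value field) get
#' `observed_mask = FALSE` and an `NA` value; row and feature order follow the
#' manifest. The per-patient sequence length is the number of label rows.
#' `groundtruth.json` files emitted by the synthetic generator are never read by
#' this loader, so simulation ground truth cannot leak into a training path.
#'
#' @param path dataset directory.
#' @return an [institution_dataset()].
#' @export
load_institution_dataset <- function(path) {
  need <- c("manifest.json", "timeseries.csv", "demographics.csv", "labels.csv")
  for (f in need) {
    if (!file.exists(file.path(path, f)))
      stop("institution dataset at '", path, "' is missing required file: ", f)
  }
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"))
  feats <- manifest$features
  kinds <- vapply(feats, function(f) f$kind, character(1))
  names(kinds) <- vapply(feats, function(f) f$name, character(1))
  dyn_feats <- sort(names(kinds)[kinds == "dynamic_numeric"])
  stat_feats <- sort(names(kinds)[kinds == "static_demographic"])

  ts <- read_csv_plain(file.path(path, "timeseries.csv"),
                       c("patient_id", "time_index", "feature", "value"))
  ts$value <- parse_numeric_column(ts$value, "timeseries.csv", "value")
  ts$time_index <- parse_numeric_column(ts$time_index, "timeseries.csv", "time_index")
  unknown <- setdiff(unique(ts$feature), dyn_feats)
  if (length(unknown))
    stop("timeseries.csv contains feature(s) absent from manifest: ",
         paste(unknown, collapse = ", "))

  demo <- read_csv_plain(file.path(path, "demographics.csv"),
                         c("patient_id", stat_feats))
  for (sf in stat_feats)
    demo[[sf]] <- parse_numeric_column(demo[[sf]], "demographics.csv", sf)

  lab <- read_csv_plain(file.path(path, "labels.csv"),
                        c("patient_id", "time_index", "mortality", "los_remaining"))
  lab$time_index <- parse_numeric_column(lab$time_index, "labels.csv", "time_index")
  lab$mortality <- parse_numeric_column(lab$mortality, "labels.csv", "mortality")
  lab$los_remaining <- parse_numeric_column(lab$los_remaining, "labels.csv", "los_remaining")

  pids <- unique(lab$patient_id)
  ts_by_pid <- split(ts, factor(ts$patient_id, levels = pids))
  lab_by_pid <- split(lab, factor(lab$patient_id, levels = pids))
  demo_idx <- match(pids, demo$patient_id)
  if (anyNA(demo_idx))
    stop("demographics.csv is missing patient(s): ",
         paste(pids[is.na(demo_idx)], collapse = ", "))

  records <- vector("list", length(pids))
  for (i in seq_along(pids)) {
    pid <- pids[i]
    plab <- lab_by_pid[[i]]
    plab <- plab[order(plab$time_index), , drop = FALSE]
    T_len <- nrow(plab)
    dyn <- matrix(NA_real_, length(dyn_feats), T_len,
                  dimnames = list(dyn_feats, NULL))
    obs <- matrix(FALSE, length(dyn_feats), T_len,
                  dimnames = list(dyn_feats, NULL))
    pts <- ts_by_pid[[i]]
    if (!is.null(pts) && nrow(pts)) {
      if (any(pts$time_index < 0 | pts$time_index >= T_len))
        stop("timeseries.csv time_index out of label range for patient ", pid)
      idx <- cbind(match(pts$feature, dyn_feats), pts$time_index + 1L)
      keep <- !is.na(pts$value)
      dyn[idx[keep, , drop = FALSE]] <- pts$value[keep]
      obs[idx[keep, , drop = FALSE]] <- TRUE
    }
    demov <- as.numeric(demo[demo_idx[i], stat_feats])
    names(demov) <- stat_feats
    los <- plab$los_remaining
    records[[i]] <- patient_record(
      patient_id = pid, dynamics = dyn, observed_mask = obs,
      demographics = demov,
      mortality = plab$mortality[1],
      los_remaining = if (all(is.na(los))) NULL else los)
  }

  institution_dataset(
    institution_id = manifest$institution_id,
    task = manifest$task,
    dynamic_features = dyn_feats,
    static_features = stat_feats,
    records = records,
    standardized = isTRUE(manifest$standardized))
}

read_csv_plain <- function(file, expected_cols) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE, colClasses = "character",
                        na.strings = "", fileEncoding = "UTF-8",
                        check.names = FALSE)
  missing <- setdiff(expected_cols, names(df))
  if (length(missing))
    stop(basename(file), " is missing column(s): ", paste(missing, collapse = ", "))
  df
}

parse_numeric_column <- function(x, file, col) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop("non-numeric value in ", file, " column '", col, "' at data row ",
         bad[1], ": '", x[bad[1]], "'")
  out
}
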