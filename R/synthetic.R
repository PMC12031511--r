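#' Configuration for the synthetic multi-institution cohort generator
#'
#' The generator emulates the heterogeneity structure of a real hospital
#' federation: several institutions with partially overlapping dynamic feature
#' sets (a Venn structure with an all-sites core, pairwise-only blocks, and
#' per-site private blocks), two demographics common to all sites (age,
#' gender), variable-length visit sequences, imbalanced terminal mortality, and
#' a remaining-length-of-stay regression target. All sites' features read out
#' a patient-level latent risk trajectory, so cross-site knowledge transfer
#' through shared feature channels is genuinely informative.
#'
#' @param n_institutions number of sites.
#' @param n_patients integer vector, patients per site.
#' @param n_shared_features dynamic features recorded by every site.
#' @param n_pairwise_features dynamic features per unordered site pair,
#'   recorded by exactly that pair.
#' @param n_private_features dynamic features private to each site.
#' @param T_range `(min, max)` visit-sequence length, inclusive.
#' @param latent_dim dimension of the latent risk state.
#' @param effect_weights numeric vector (length `latent_dim`) mapping the
#'   terminal latent state to the outcome logit.
#' @param mortality_base_rate target marginal event rate in (0, 1).
#' @param noise_sd observation noise s.d. on every dynamic feature.
#' @param missing_rate i.i.d. probability that an observation is dropped.
#' @param latent_step_sd s.d. of each Gaussian random-walk increment.
#' @param tasks character vector per site: `"mortality"`, `"los"` or `"both"`.
#' @param seed integer master seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_institutions,
                          n_patients,
                          n_shared_features,
                          n_pairwise_features,
                          n_private_features,
                          T_range = c(4L, 12L),
                          latent_dim = 3L,
                          effect_weights = c(1.5, 1.0, -1.0),
                          mortality_base_rate = 0.15,
                          noise_sd = 1.0,
                          missing_rate = 0.3,
                          latent_step_sd = 0.35,
                          tasks = rep("both", n_institutions),
                          seed = 1L) {
  stopifnot(n_institutions >= 1,
            length(n_patients) == n_institutions,
            all(n_patients >= 1),
            n_shared_features >= 1,  # pairwise overlap must be non-empty
            n_pairwise_features >= 0, n_private_features >= 0,
            length(T_range) == 2, T_range[1] >= 1, T_range[2] >= T_range[1],
            latent_dim >= 1,
            length(effect_weights) == latent_dim,
            mortality_base_rate > 0, mortality_base_rate < 1,
            noise_sd >= 0, missing_rate >= 0, missing_rate < 1,
            length(tasks) == n_institutions)
  if (n_pairwise_features > 0 && n_institutions < 2)
    stop("pairwise feature groups need at least 2 institutions")
  tasks <- vapply(tasks, function(t)
    match.arg(t, c("mortality", "los", "both")), character(1))
  structure(
    list(n_institutions = as.integer(n_institutions),
         n_patients = as.integer(n_patients),
         n_shared_features = as.integer(n_shared_features),
         n_pairwise_features = as.integer(n_pairwise_features),
         n_private_features = as.integer(n_private_features),
         T_range = as.integer(T_range),
         latent_dim = as.integer(latent_dim),
         effect_weights = as.numeric(effect_weights),
         mortality_base_rate = mortality_base_rate,
         noise_sd = noise_sd,
         missing_rate = missing_rate,
         latent_step_sd = latent_step_sd,
         tasks = unname(tasks),
         seed = as.integer(seed)),
    class = "cohort_config")
}

#' Default three-institution study configuration
#'
#' Mirrors a federation of one small, one large and one medium cohort with
#' asymmetric sample sizes (400 / 1500 / 600 patients), a feature Venn of 8
#' all-shared, 4 per pairwise intersection and 4 private features per site
#' (32 dynamic features in total), two shared demographics, and a task split
#' in which the first two sites predict both mortality and remaining length of
#' stay while the third predicts mortality only.
#'
#' @param seed master seed.
#' @return a [cohort_config()].
#' @export
default_study_config <- function(seed = 1L) {
  cohort_config(
    n_institutions = 3L,
    n_patients = c(400L, 1500L, 600L),
    n_shared_features = 8L,
    n_pairwise_features = 4L,
    n_private_features = 4L,
    tasks = c("both", "both", "mortality"),
    seed = seed)
}

site_ids <- function(n) sprintf("site%d", seq_len(n))

#' Feature manifest induced by a cohort configuration
#'
#' Realizes the configured Venn structure with deterministic feature names:
#' `shared_f*` for the all-sites core, `pair_<i>_<j>_f*` for each pairwise-only
#' block, `private_<site>_f*` for private blocks; demographics `age` and
#' `gender` at every site.
#'
#' @param config a [cohort_config()].
#' @return a [feature_manifest()].
#' @export
cohort_manifest <- function(config) {
  ids <- site_ids(config$n_institutions)
  recorded <- stats::setNames(
    lapply(ids, function(i) c("age", "gender")), ids)
  kinds <- c(age = "static_demographic", gender = "static_demographic")
  add <- function(feats, sites) {
    for (s in sites) recorded[[s]] <<- c(recorded[[s]], feats)
    kinds[feats] <<- "dynamic_numeric"
  }
  if (config$n_shared_features > 0)
    add(sprintf("shared_f%02d", seq_len(config$n_shared_features)), ids)
  if (config$n_pairwise_features > 0 && config$n_institutions >= 2) {
    pairs <- utils::combn(config$n_institutions, 2)
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]; j <- pairs[2, p]
      add(sprintf("pair_%d_%d_f%02d", i, j, seq_len(config$n_pairwise_features)),
          ids[c(i, j)])
    }
  }
  if (config$n_private_features > 0) {
    for (k in seq_along(ids))
      add(sprintf("private_%s_f%02d", ids[k], seq_len(config$n_private_features)),
          ids[k])
  }
  feature_manifest(recorded, kinds)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Calibrate the outcome-logit intercept by bisection so the marginal event
# rate under the generative model matches the target, using a Monte Carlo
# sample of terminal latent states at a fixed internal seed.
calibrate_intercept <- function(config, n_mc = 10000L) {
  risk <- with_preserved_rng({
    set.seed(271828L)
    T_mc <- sample(seq(config$T_range[1], config$T_range[2]), n_mc, replace = TRUE)
    zT <- matrix(stats::rnorm(n_mc * config$latent_dim), n_mc, config$latent_dim)
    zT <- zT + matrix(stats::rnorm(n_mc * config$latent_dim), n_mc,
                      config$latent_dim) * config$latent_step_sd * sqrt(pmax(T_mc - 1, 0))
    age_std <- stats::runif(n_mc, -1, 1)  # matches (age - 56.5)/38.5 under U(18, 95)
    gender <- stats::rbinom(n_mc, 1, 0.5)
    drop(zT %*% config$effect_weights) + 0.3 * age_std + 0.1 * (gender - 0.5)
  })
  f <- function(b) mean(sigmoid(b + risk)) - config$mortality_base_rate
  stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}

with_preserved_rng <- function(expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Generate synthetic institution cohorts
#'
#' Generative model, per patient: the latent risk state `z_t` follows a
#' Gaussian random walk of dimension `latent_dim` (`z_1 ~ N(0, I)`, increments
#' `N(0, latent_step_sd^2 I)`); each dynamic feature is a fixed random linear
#' readout of `z_t` plus `noise_sd` Gaussian noise, with the readout vector
#' drawn once per *feature name*, so the same feature carries the same signal
#' at every site that records it; the terminal mortality label is
#' `Bernoulli(sigmoid(intercept + effect_weights . z_T + 0.3 age_std +
#' 0.1 (gender - 0.5)))` with the intercept calibrated by bisection to the
#' target base rate; the remaining length of stay decreases by exactly one day
#' per record index down to a terminal remainder that shortens with terminal
#' risk; observations are dropped i.i.d. at `missing_rate`.
#'
#' @param config a [cohort_config()].
#' @return list with `datasets` (list of [institution_dataset()], raw scale),
#'   `manifest` (the federation [feature_manifest()]) and `ground_truth`
#'   (per-site latent trajectories, readout matrix, true event probabilities —
#'   for parameter-recovery tests only, never a training input).
#' @export
generate_cohorts <- function(config) {
  ids <- site_ids(config$n_institutions)
  manifest <- cohort_manifest(config)
  intercept <- calibrate_intercept(config)
  set.seed(config$seed)

  dyn_all <- canonical_dynamic_features(manifest)
  # one readout per canonical feature name, shared across sites
  readout <- matrix(stats::rnorm(length(dyn_all) * config$latent_dim),
                    nrow = length(dyn_all),
                    dimnames = list(dyn_all, NULL))

  datasets <- vector("list", config$n_institutions)
  names(datasets) <- ids
  gt_sites <- vector("list", config$n_institutions)
  names(gt_sites) <- ids

  for (k in seq_along(ids)) {
    inst <- ids[k]
    feats <- institution_dynamic_features(manifest, inst)
    A <- readout[feats, , drop = FALSE]
    n <- config$n_patients[k]
    records <- vector("list", n)
    gt <- vector("list", n)
    for (p in seq_len(n)) {
      pid <- sprintf("%s_p%04d", inst, p)
      T_len <- sample(seq(config$T_range[1], config$T_range[2]), 1)
      z <- matrix(0, config$latent_dim, T_len)
      z[, 1] <- stats::rnorm(config$latent_dim)
      if (T_len > 1)
        for (t in 2:T_len)
          z[, t] <- z[, t - 1] + stats::rnorm(config$latent_dim, sd = config$latent_step_sd)
      vals <- A %*% z +
        matrix(stats::rnorm(length(feats) * T_len, sd = config$noise_sd),
               length(feats), T_len)
      rownames(vals) <- feats
      obs <- matrix(stats::runif(length(feats) * T_len) >= config$missing_rate,
                    length(feats), T_len, dimnames = list(feats, NULL))
      vals[!obs] <- NA_real_

      age <- stats::runif(1, 18, 95)
      gender <- stats::rbinom(1, 1, 0.5)
      age_std <- (age - 56.5) / 38.5
      risk_T <- sum(config$effect_weights * z[, T_len])
      p_event <- sigmoid(intercept + risk_T + 0.3 * age_std + 0.1 * (gender - 0.5))
      mortality <- stats::rbinom(1, 1, p_event)

      task <- config$tasks[k]
      los <- NULL
      if (task %in% c("los", "both")) {
        # remaining stay after the last record shortens with terminal risk;
        # within the observed window it decrements exactly one day per record
        tail_days <- max(0, round(6 - 2 * risk_T))
        los <- tail_days + rev(seq_len(T_len)) - 1
      }
      records[[p]] <- patient_record(
        patient_id = pid,
        dynamics = vals,
        observed_mask = obs,
        demographics = c(age = age, gender = as.numeric(gender)),
        mortality = if (task %in% c("mortality", "both")) mortality else NA_real_,
        los_remaining = los)
      gt[[p]] <- list(patient_id = pid, z = z, p_event = p_event,
                      mortality = mortality)
    }
    datasets[[k]] <- institution_dataset(
      institution_id = inst,
      task = config$tasks[k],
      dynamic_features = feats,
      static_features = c("age", "gender"),
      records = records)
    gt_sites[[k]] <- gt
  }

  list(datasets = datasets,
       manifest = manifest,
       ground_truth = list(readout = readout, intercept = intercept,
                           sites = gt_sites))
}

#' Write generated cohorts to institution dataset directories
#'
#' One subdirectory per site in the exchange format of
#' [write_institution_dataset()], plus `groundtruth.json` (true event
#' probabilities and intercept; excluded from any training path — the loader
#' never reads it) and `run_manifest.json` echoing the configuration and seed.
#'
#' @param cohorts output of [generate_cohorts()].
#' @param out_dir output directory.
#' @param config the [cohort_config()] used (echoed into the run manifest).
#' @return character vector of site directories, invisibly.
#' @export
write_cohorts <- function(cohorts, out_dir, config = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dirs <- character(length(cohorts$datasets))
  for (i in seq_along(cohorts$datasets)) {
    ds <- cohorts$datasets[[i]]
    dirs[i] <- file.path(out_dir, ds$institution_id)
    write_institution_dataset(ds, dirs[i])
  }
  gt <- list(
    intercept = cohorts$ground_truth$intercept,
    sites = lapply(cohorts$ground_truth$sites, function(site)
      lapply(site, function(g)
        list(patient_id = g$patient_id, p_event = g$p_event))))
  jsonlite::write_json(gt, file.path(out_dir, "groundtruth.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(config))
    jsonlite::write_json(list(config = unclass(config),
                              package_version = as.character(utils::packageVersion("fedprog"))),
                         file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dirs)
}
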