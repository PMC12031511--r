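# Independent oracles used across the suite. These deliberately re-derive
# quantities with naive scalar loops / enumeration, never by calling the
# package's vectorized implementations.

# Step-by-step scalar recurrence for one gated channel: plain loops over
# hidden units, mirroring the documented gate equations.
gru_scalar_oracle <- function(params, series) {
  h <- length(params$bz)
  hid <- rep(0, h)
  for (x in series) {
    z <- r <- cand <- rep(0, h)
    for (k in seq_len(h)) {
      az <- params$Wz[k] * x + sum(params$Uz[k, ] * hid) + params$bz[k]
      ar <- params$Wr[k] * x + sum(params$Ur[k, ] * hid) + params$br[k]
      z[k] <- 1 / (1 + exp(-az))
      r[k] <- 1 / (1 + exp(-ar))
    }
    for (k in seq_len(h)) {
      ac <- params$Wh[k] * x + sum(params$Uh[k, ] * (r * hid)) + params$bh[k]
      cand[k] <- tanh(ac)
    }
    hid <- (1 - z) * hid + z * cand
  }
  hid
}

# AUROC by brute force over all positive-negative pairs.
auroc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Average precision from the PR step curve, walking distinct thresholds and
# recomputing precision/recall from scratch at each.
auprc_stepcurve_oracle <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  ap <- 0; prev_recall <- 0
  for (t in th) {
    sel <- scores >= t
    prec <- sum(labels[sel] == 1) / sum(sel)
    recall <- sum(labels[sel] == 1) / n_pos
    ap <- ap + (recall - prev_recall) * prec
    prev_recall <- recall
  }
  ap
}

# Pooled population moments computed directly on the concatenated values.
pooled_moments_oracle <- function(values) {
  list(count = length(values), mean = mean(values),
       std = sqrt(mean((values - mean(values))^2)))
}

# A small hand-built two-site federation used by several files.
tiny_manifest <- function() {
  feature_manifest(
    recorded_by = list(
      A = c("age", "gender", "crp", "urea", "hr"),
      B = c("age", "gender", "crp", "wbc")),
    kinds = c(age = "static_demographic", gender = "static_demographic",
              crp = "dynamic_numeric", urea = "dynamic_numeric",
              hr = "dynamic_numeric", wbc = "dynamic_numeric"))
}

tiny_record <- function(pid, feats, T_len, mortality = 0, los = NULL,
                        seed = 1) {
  set.seed(seed)
  dyn <- matrix(rnorm(length(feats) * T_len), length(feats), T_len,
                dimnames = list(feats, NULL))
  obs <- matrix(TRUE, length(feats), T_len, dimnames = list(feats, NULL))
  patient_record(pid, dyn, obs, c(age = 60, gender = 1),
                 mortality = mortality, los_remaining = los)
}

# Small standardized synthetic federation for integration-level tests.
tiny_cohort <- function(seed = 7, n = c(20, 24), T_range = c(2, 4)) {
  cfg <- cohort_config(
    n_institutions = 2, n_patients = n, n_shared_features = 2,
    n_pairwise_features = 0, n_private_features = 1, T_range = T_range,
    tasks = c("both", "mortality"), seed = seed)
  generate_cohorts(cfg)
}
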