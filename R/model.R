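# Site model = per-feature recurrent channels (recorded features only),
# demographic embedding, per-row recalibration projections, task heads.
# Parameters flatten to a keyed list ("channel.<feature>.<gate>",
# "demographic.W_base", "recalib.<row>.<Wq|Wk|Wv>", "head.<name>") so the
# federation layer can tag every key shared or private and exchange flat
# parameter/gradient messages only.

GATE_NAMES <- c("Wz", "Wr", "Wh", "Uz", "Ur", "Uh", "bz", "br", "bh")

# Deterministic 32-bit child seed from a master seed and a string tag, so all
# randomness (init, splits, shuffles, dropout) fans out reproducibly and
# identically across federation modes.
derive_seed <- function(seed, tag) {
  M <- 2147483647
  acc <- as.numeric(seed) %% M
  for (ch in utf8ToInt(tag)) acc <- (acc * 31 + ch) %% M
  as.integer(acc %% (M - 1) + 1)
}

#' Initialize a site model
#'
#' Channel parameters and the demographic embedding are drawn from a stream
#' seeded only by the master seed and the feature name, so every site starts
#' with bit-identical parameters for the features it shares with others — the
#' premise of collaborative channel training. Recalibration projections and
#' task heads are private and seeded per site.
#'
#' @param manifest the federation [feature_manifest()].
#' @param institution_id site whose model to build (must appear in the
#'   manifest, or be `"central"` to record every feature).
#' @param task `"mortality"`, `"los"` or `"both"`.
#' @param h hidden dimension (default 32).
#' @param seed master seed.
#' @return object of class `site_model`.
#' @export
init_site_model <- function(manifest, institution_id, task, h = 32L, seed = 1L) {
  central <- identical(institution_id, "central")
  feats <- if (central) canonical_dynamic_features(manifest)
           else institution_dynamic_features(manifest, institution_id)
  statics <- if (central) {
    manifest$feature_names[manifest$feature_kind == "static_demographic"]
  } else institution_static_features(manifest, institution_id)
  rows <- canonical_rows(manifest)

  channels <- vector("list", length(feats))
  names(channels) <- feats
  for (f in feats)
    channels[[f]] <- with_preserved_rng({
      set.seed(derive_seed(seed, paste0("channel:", f)))
      init_gru_params(h)
    })
  W_base <- with_preserved_rng({
    set.seed(derive_seed(seed, "demographic"))
    lim <- 1 / sqrt(h)
    matrix(stats::runif(h * length(statics), -lim, lim), h, length(statics),
           dimnames = list(NULL, statics))
  })
  private <- with_preserved_rng({
    set.seed(derive_seed(seed, paste0("private:", institution_id)))
    list(recalib = init_recalibration_params(rows, h),
         head = init_head_params(h))
  })
  recorded_rows <- stats::setNames(rows %in% c(feats, DEMOGRAPHIC_ROW), rows)
  structure(
    list(institution_id = institution_id, task = task, h = as.integer(h),
         rows = rows, recorded_rows = recorded_rows,
         dynamic_features = feats, static_features = statics,
         channels = channels, W_base = W_base,
         recalib = private$recalib, head = private$head),
    class = "site_model")
}

#' Flatten a site model's parameters to a keyed list
#' @param model a `site_model`.
#' @return named list of numeric arrays.
#' @export
flatten_site_params <- function(model) {
  out <- list()
  for (f in names(model$channels))
    for (g in GATE_NAMES)
      out[[paste0("channel.", f, ".", g)]] <- model$channels[[f]][[g]]
  out[["demographic.W_base"]] <- model$W_base
  for (r in names(model$recalib))
    for (nm in c("Wq", "Wk", "Wv"))
      out[[paste0("recalib.", r, ".", nm)]] <- model$recalib[[r]][[nm]]
  for (nm in names(model$head))
    out[[paste0("head.", nm)]] <- model$head[[nm]]
  out
}

#' Write flat parameter values back into a site model
#' @param model a `site_model`.
#' @param flat named list of arrays; only keys present are assigned.
#' @return the updated model.
#' @export
set_site_params <- function(model, flat) {
  for (key in names(flat)) {
    if (startsWith(key, "channel.")) {
      rest <- substring(key, nchar("channel.") + 1)
      g <- sub("^.*\\.", "", rest)
      f <- substring(rest, 1, nchar(rest) - nchar(g) - 1)
      if (!is.null(model$channels[[f]])) model$channels[[f]][[g]] <- flat[[key]]
    } else if (key == "demographic.W_base") {
      model$W_base <- flat[[key]]
    } else if (startsWith(key, "recalib.")) {
      rest <- substring(key, nchar("recalib.") + 1)
      nm <- sub("^.*\\.", "", rest)
      r <- substring(rest, 1, nchar(rest) - nchar(nm) - 1)
      if (!is.null(model$recalib[[r]])) model$recalib[[r]][[nm]] <- flat[[key]]
    } else if (startsWith(key, "head.")) {
      model$head[[substring(key, 6)]] <- flat[[key]]
    }
  }
  model
}

# Fixed documented transform for the two standard demographics: age is mapped
# from its adult range onto roughly [-1, 1]; gender codes pass through.
standardize_demographics <- function(demo) {
  if ("age" %in% names(demo)) demo[["age"]] <- (demo[["age"]] - 56.5) / 38.5
  demo
}

#' Pack a standardized, imputed dataset into padded training tensors
#'
#' @param dataset standardized + imputed [institution_dataset()].
#' @return list with per-feature `[n x Tmax]` value and observation matrices,
#'   sequence lengths, transformed demographics, and label tensors.
#' @export
prepare_site_tensors <- function(dataset) {
  if (!isTRUE(dataset$standardized))
    stop("tensors must be built from a standardized dataset")
  feats <- dataset$dynamic_features
  n <- n_patients(dataset)
  L <- vapply(dataset$records, function(r) ncol(r$dynamics), integer(1))
  Tmax <- max(L)
  X <- lapply(feats, function(f) matrix(0, n, Tmax))
  names(X) <- feats
  OBS <- lapply(feats, function(f) matrix(FALSE, n, Tmax))
  names(OBS) <- feats
  Base <- matrix(0, n, length(dataset$static_features),
                 dimnames = list(NULL, dataset$static_features))
  y_mort <- rep(NA_real_, n)
  Y_los <- matrix(NA_real_, n, Tmax)
  for (i in seq_len(n)) {
    r <- dataset$records[[i]]
    for (f in feats) {
      X[[f]][i, seq_len(L[i])] <- r$dynamics[f, ]
      OBS[[f]][i, seq_len(L[i])] <- r$observed_mask[f, ]
    }
    demo <- standardize_demographics(r$demographics)
    Base[i, ] <- as.numeric(demo[dataset$static_features])
    y_mort[i] <- r$mortality
    if (!is.null(r$los_remaining)) Y_los[i, seq_len(L[i])] <- r$los_remaining
  }
  list(feats = feats, n = n, L = L, Tmax = Tmax, X = X, OBS = OBS,
       Base = Base, y_mort = y_mort, Y_los = Y_los,
       patient_ids = vapply(dataset$records, `[[`, "", "patient_id"),
       task = dataset$task)
}

# Record index set for a patient subset: for regression tasks every (patient,
# time) pair is a supervised record (prefix encoding — the representation at
# record t only sees data up to t); classification-only sites need the final
# record per patient.
record_index <- function(L, per_record) {
  if (per_record) {
    list(p = rep(seq_along(L), L), t = sequence(L),
         last = sequence(L) == rep(L, L))
  } else {
    list(p = seq_along(L), t = L, last = rep(TRUE, length(L)))
  }
}

#' Batched forward/backward pass for one site mini-batch
#'
#' Runs every recorded feature channel over the batch, builds per-record
#' feature matrices, applies masked-attention recalibration and the site's
#' task heads, and (optionally) backpropagates to produce flat keyed
#' gradients. The gradient list contains keys only for parameters the site
#' actually uses (freeze-and-mask: unrecorded features contribute no keys).
#'
#' @param model a `site_model`.
#' @param tensors output of [prepare_site_tensors()].
#' @param idx integer patient indices of the mini-batch.
#' @param train logical: apply dropout.
#' @param dropout dropout rate on the demographic row (active only when
#'   `train = TRUE`).
#' @param compute_grads logical.
#' @param rng_seed integer seed for the dropout mask (ignored if not training).
#' @return list: `loss`, `loss_cla`, `loss_reg`, `p_mort`, `y_mort`,
#'   `los_pred`, `los_true`, `alpha_last` (attention weights at each
#'   patient's final record, `[B x n_rows]`), and `grads` (flat keyed list)
#'   when requested.
#' @export
site_forward <- function(model, tensors, idx = seq_len(tensors$n),
                         train = FALSE, dropout = 0.1,
                         compute_grads = FALSE, rng_seed = 1L) {
  feats <- tensors$feats
  B <- length(idx)
  L <- tensors$L[idx]
  Tmax <- max(L)
  h <- model$h
  per_record <- model$task %in% c("los", "both")
  ri <- record_index(L, per_record)
  n_rec <- length(ri$p)

  # --- channels ---
  fwd <- vector("list", length(feats)); names(fwd) <- feats
  F_rows <- vector("list", length(feats)); names(F_rows) <- feats
  t_sel <- split(seq_len(n_rec), ri$t)  # record rows grouped by time index
  for (f in feats) {
    Xb <- tensors$X[[f]][idx, seq_len(Tmax), drop = FALSE]
    fw <- gru_forward(model$channels[[f]], Xb, L)
    Ff <- matrix(0, n_rec, h)
    for (tc in names(t_sel)) {
      tt <- as.integer(tc)
      sel <- t_sel[[tc]]
      Ff[sel, ] <- fw$H[[tt + 1]][ri$p[sel], , drop = FALSE]
    }
    fwd[[f]] <- fw
    F_rows[[f]] <- Ff
  }

  # --- demographic row: linear embed, GELU, (inverted) dropout ---
  Base_b <- tensors$Base[idx, , drop = FALSE]
  pre <- tcrossprod(Base_b, model$W_base)       # [B x h]
  Dem <- gelu(pre)
  if (train && dropout > 0) {
    keep <- with_preserved_rng({
      set.seed(rng_seed)
      matrix(stats::runif(B * h) >= dropout, B, h)
    })
    drop_scale <- keep / (1 - dropout)
    Dem <- Dem * drop_scale
  } else drop_scale <- NULL
  Dem_rec <- Dem[ri$p, , drop = FALSE]

  # --- context: mean of recorded rows ---
  n_rows_rec <- length(feats) + 1
  f_bar <- Dem_rec
  for (f in feats) f_bar <- f_bar + F_rows[[f]]
  f_bar <- f_bar / n_rows_rec

  # --- masked attention (unrecorded rows carry MASK_VALUE, weight 0) ---
  rec_rows <- c(feats, DEMOGRAPHIC_ROW)
  row_F <- c(F_rows, stats::setNames(list(Dem_rec), DEMOGRAPHIC_ROW))
  Q <- K <- V <- vector("list", length(rec_rows))
  names(Q) <- names(K) <- names(V) <- rec_rows
  zeta <- matrix(0, n_rec, length(rec_rows))
  for (j in seq_along(rec_rows)) {
    r <- rec_rows[j]
    p <- model$recalib[[r]]
    Q[[r]] <- tcrossprod(f_bar, p$Wq)
    K[[r]] <- tcrossprod(row_F[[r]], p$Wk)
    V[[r]] <- tcrossprod(row_F[[r]], p$Wv)
    zeta[, j] <- rowSums(Q[[r]] * K[[r]])
  }
  zmax <- zeta[cbind(seq_len(n_rec), max.col(zeta, ties.method = "first"))]
  E <- exp(zeta - zmax)
  alpha <- E / rowSums(E)                       # [n_rec x recorded rows]
  s <- matrix(0, n_rec, h)
  for (j in seq_along(rec_rows)) s <- s + alpha[, j] * V[[rec_rows[j]]]

  # --- heads and losses ---
  out <- list(loss = 0, loss_cla = NA_real_, loss_reg = NA_real_)
  ds <- matrix(0, n_rec, h)
  has_cla <- model$task %in% c("mortality", "both") &&
    !all(is.na(tensors$y_mort[idx]))
  if (has_cla) {
    last_rows <- which(ri$last)
    s_cla <- s[last_rows, , drop = FALSE]
    y <- tensors$y_mort[idx]
    pr <- predict_classification(model$head, s_cla)
    out$loss_cla <- bce_loss(pr, y)
    out$p_mort <- pr
    out$y_mort <- y
    out$loss <- out$loss + out$loss_cla
  }
  has_reg <- model$task %in% c("los", "both")
  if (has_reg) {
    # train against the standardized target so both task losses share a
    # scale; report predictions in days
    ctr <- if (is.null(tensors$los_center)) 0 else tensors$los_center
    scl <- if (is.null(tensors$los_scale)) 1 else tensors$los_scale
    y_days <- tensors$Y_los[idx, , drop = FALSE][cbind(ri$p, ri$t)]
    y_rec <- (y_days - ctr) / scl
    ok <- !is.na(y_rec)
    pred <- predict_regression(model$head, s)
    out$loss_reg <- mse_loss(pred[ok], y_rec[ok])
    out$los_pred <- pred * scl + ctr
    out$los_true <- y_days
    out$loss <- out$loss + out$loss_reg
  }
  out$alpha_last <- {
    al <- matrix(0, B, length(model$rows),
                 dimnames = list(tensors$patient_ids[idx], model$rows))
    al[, rec_rows] <- alpha[which(ri$last), , drop = FALSE]
    al
  }
  out$record_p <- ri$p; out$record_t <- ri$t

  if (!compute_grads) return(out)

  # ===== backward =====
  if (has_cla) {
    dlogit <- (out$p_mort - out$y_mort) / length(out$y_mort)
    ds[which(ri$last), ] <- ds[which(ri$last), , drop = FALSE] +
      outer(dlogit, model$head$W_cla)
    gW_cla <- drop(crossprod(s[which(ri$last), , drop = FALSE], dlogit))
    gb_cla <- sum(dlogit)
  } else { gW_cla <- numeric(h); gb_cla <- 0 }
  if (has_reg) {
    y_rec <- (out$los_true - ctr) / scl
    ok <- !is.na(y_rec)
    dpred <- numeric(n_rec)
    dpred[ok] <- 2 * ((out$los_pred[ok] - ctr) / scl - y_rec[ok]) / sum(ok)
    ds <- ds + outer(dpred, model$head$W_reg)
    gW_reg <- drop(crossprod(s, dpred))
    gb_reg <- sum(dpred)
  } else { gW_reg <- numeric(h); gb_reg <- 0 }

  grads <- list()
  grads[["head.W_cla"]] <- gW_cla; grads[["head.b_cla"]] <- gb_cla
  grads[["head.W_reg"]] <- gW_reg; grads[["head.b_reg"]] <- gb_reg

  # attention backward
  dalpha <- matrix(0, n_rec, length(rec_rows))
  dF <- vector("list", length(rec_rows)); names(dF) <- rec_rows
  for (j in seq_along(rec_rows)) {
    r <- rec_rows[j]
    dV <- ds * alpha[, j]
    grads[[paste0("recalib.", r, ".Wv")]] <- crossprod(dV, row_F[[r]])
    dF[[r]] <- dV %*% model$recalib[[r]]$Wv
    dalpha[, j] <- rowSums(ds * V[[r]])
  }
  dzeta <- alpha * (dalpha - rowSums(alpha * dalpha))
  dfbar <- matrix(0, n_rec, h)
  for (j in seq_along(rec_rows)) {
    r <- rec_rows[j]
    dQ <- dzeta[, j] * K[[r]]
    dK <- dzeta[, j] * Q[[r]]
    grads[[paste0("recalib.", r, ".Wq")]] <- crossprod(dQ, f_bar)
    grads[[paste0("recalib.", r, ".Wk")]] <- crossprod(dK, row_F[[r]])
    dfbar <- dfbar + dQ %*% model$recalib[[r]]$Wq
    dF[[r]] <- dF[[r]] + dK %*% model$recalib[[r]]$Wk
  }
  dfbar_share <- dfbar / n_rows_rec
  for (r in rec_rows) dF[[r]] <- dF[[r]] + dfbar_share

  # demographic row backward
  dDem_rec <- dF[[DEMOGRAPHIC_ROW]]
  dDem <- rowsum(dDem_rec, ri$p, reorder = TRUE)
  if (!is.null(drop_scale)) dDem <- dDem * drop_scale
  dPre <- dDem * gelu_grad(pre)
  grads[["demographic.W_base"]] <- crossprod(dPre, Base_b)

  # channel backward (BPTT), scattering record-row gradients to time steps
  for (f in feats) {
    dH_out <- vector("list", Tmax)
    dFf <- dF[[f]]
    for (tc in names(t_sel)) {
      tt <- as.integer(tc)
      sel <- t_sel[[tc]]
      m <- matrix(0, B, h)
      m[ri$p[sel], ] <- dFf[sel, , drop = FALSE]
      dH_out[[tt]] <- m
    }
    g <- gru_backward(model$channels[[f]], fwd[[f]], dH_out)
    for (gn in GATE_NAMES) grads[[paste0("channel.", f, ".", gn)]] <- g[[gn]]
  }
  out$grads <- grads
  out
}
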