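#' Shared/private parameter partition induced by the feature manifest
#'
#' A dynamic feature's channel is shared iff at least two institutions record
#' the feature; the demographic embedding is shared iff the demographic schema
#' is common to all sites; recalibration projections and task heads are always
#' private. If no feature is recorded by two or more sites, the shared set is
#' empty and a warning is emitted: federation degenerates to isolated
#' training, no transfer is possible.
#'
#' @param manifest the federation [feature_manifest()].
#' @return list with `shared_keys` (character) and `private_keys` (named list
#'   per institution).
#' @export
partition_parameters <- function(manifest) {
  insts <- names(manifest$recorded_by)
  shared_dyn <- shared_features(manifest, kind = "dynamic_numeric")
  shared_keys <- as.character(unlist(lapply(
    shared_dyn, function(f) paste0("channel.", f, ".", GATE_NAMES))))
  statics <- lapply(insts, function(i) institution_static_features(manifest, i))
  demo_shared <- length(insts) >= 2 &&
    all(vapply(statics, function(s) identical(s, statics[[1]]), logical(1)))
  if (demo_shared || length(insts) == 1)
    shared_keys <- c(shared_keys, "demographic.W_base")
  if (length(shared_dyn) == 0 && length(insts) >= 2)
    warning("no feature is recorded by two or more institutions: ",
            "no cross-site transfer is possible")
  rows <- canonical_rows(manifest)
  private_keys <- lapply(insts, function(i) {
    own_dyn <- institution_dynamic_features(manifest, i)
    priv_dyn <- setdiff(own_dyn, shared_dyn)
    c(as.character(unlist(lapply(priv_dyn, function(f)
        paste0("channel.", f, ".", GATE_NAMES)))),
      if (!demo_shared && length(insts) >= 2) "demographic.W_base",
      as.character(unlist(lapply(rows, function(r)
        paste0("recalib.", r, ".", c("Wq", "Wk", "Wv"))))),
      paste0("head.", c("W_cla", "b_cla", "W_reg", "b_reg")))
  })
  names(private_keys) <- insts
  list(shared_keys = shared_keys, private_keys = private_keys)
}

#' Count-weighted federated averaging of shared parameters
#'
#' For each shared key, the average runs over the sites that hold the key
#' (a feature shared by two of three sites is averaged over those two),
#' weighted by their sample counts. Private keys are never touched.
#'
#' @param param_list named list per site of flat keyed parameter lists.
#' @param counts numeric sample counts `M_n`, same length/order.
#' @param shared_keys keys to aggregate (default: union of all keys present).
#' @return flat named list of aggregated arrays.
#' @export
fedavg_aggregate <- function(param_list, counts,
                             shared_keys = unique(unlist(lapply(param_list, names)))) {
  if (length(param_list) == 0) stop("fedavg_aggregate needs at least one client")
  stopifnot(length(counts) == length(param_list), all(counts > 0))
  out <- list()
  for (key in shared_keys) {
    have <- which(vapply(param_list, function(p) !is.null(p[[key]]), logical(1)))
    if (length(have) == 0) next
    w <- counts[have] / sum(counts[have])
    acc <- param_list[[have[1]]][[key]] * w[1]
    if (length(have) > 1)
      for (j in 2:length(have))
        acc <- acc + param_list[[have[j]]][[key]] * w[j]
    out[[key]] <- acc
  }
  out
}

#' Construct / validate a client-to-server message
#'
#' The only objects a site ever sends: a payload of keyed numeric parameter or
#' gradient arrays plus its sample count. Validation rejects any field that
#' could carry patient-level data (non-numeric entries, keys outside the
#' parameter naming scheme, extra fields).
#'
#' @param institution_id sender id.
#' @param payload_type `"params"` or `"gradient"`.
#' @param payload flat keyed list of numeric arrays.
#' @param n_samples sample count `M_n`.
#' @return validated message (class `client_message`).
#' @export
client_message <- function(institution_id, payload_type, payload, n_samples) {
  msg <- structure(list(institution_id = institution_id,
                        payload_type = payload_type,
                        payload = payload, n_samples = n_samples),
                   class = "client_message")
  validate_client_message(msg)
  msg
}

#' @rdname client_message
#' @param msg a `client_message`.
#' @export
validate_client_message <- function(msg) {
  stopifnot(identical(sort(names(unclass(msg))),
                      sort(c("institution_id", "payload_type", "payload",
                             "n_samples"))))
  if (!msg$payload_type %in% c("params", "gradient"))
    stop("unknown payload type: ", msg$payload_type)
  if (!is.numeric(msg$n_samples) || length(msg$n_samples) != 1)
    stop("n_samples must be a single count")
  ok_key <- grepl("^(channel\\..+\\.(Wz|Wr|Wh|Uz|Ur|Uh|bz|br|bh)|demographic\\.W_base|recalib\\..+\\.(Wq|Wk|Wv)|head\\.(W_cla|b_cla|W_reg|b_reg))$",
                  names(msg$payload))
  if (!all(ok_key))
    stop("payload key(s) outside the parameter naming scheme: ",
         paste(names(msg$payload)[!ok_key], collapse = ", "))
  if (!all(vapply(msg$payload, is.numeric, logical(1))))
    stop("payload must contain numeric parameter arrays only")
  invisible(msg)
}

#' Training configuration
#'
#' Defaults follow the study protocol: AdamW, learning rate 0.001, batch size
#' 1024 patients, hidden dimension 32, dropout 0.1, at most 50 epochs with
#' early stopping after 10 epochs without validation improvement, and a
#' 70/10/20 train/validation/test split.
#'
#' @param mode `"federated"`, `"isolated"` (no aggregation) or `"centralized"`
#'   (oracle upper bound: one model trained on all sites' pooled records).
#' @param fed_mode `"fedavg"` (round = `local_epochs` local epochs then
#'   count-weighted averaging of shared keys) or `"accum"` (per round, one
#'   mini-batch gradient per site is accumulated and the server takes a single
#'   optimizer step on the shared keys).
#' @param optimizer `"adamw"` or `"adam"`.
#' @param lr,weight_decay,batch_size,epochs,patience,local_epochs,h,dropout
#'   training hyperparameters.
#' @param split train/validation/test fractions (must sum to 1).
#' @param finetune_epochs local-only epochs after federation (default 0).
#' @param seed master seed; every RNG stream fans out from it.
#' @return list of class `fed_config`.
#' @export
fed_config <- function(mode = c("federated", "isolated", "centralized"),
                       fed_mode = c("fedavg", "accum"),
                       optimizer = c("adamw", "adam"),
                       lr = 1e-3, weight_decay = 0.01, batch_size = 1024L,
                       epochs = 50L, patience = 10L, local_epochs = 1L,
                       h = 32L, dropout = 0.1, split = c(0.7, 0.1, 0.2),
                       finetune_epochs = 0L, seed = 1L) {
  stopifnot(length(split) == 3, abs(sum(split) - 1) < 1e-8, all(split > 0))
  structure(list(mode = match.arg(mode), fed_mode = match.arg(fed_mode),
                 optimizer = match.arg(optimizer), lr = lr,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 local_epochs = as.integer(local_epochs), h = as.integer(h),
                 dropout = dropout, split = split,
                 finetune_epochs = as.integer(finetune_epochs),
                 seed = as.integer(seed)),
            class = "fed_config")
}

#' Seeded train/validation/test split
#' @param n number of patients.
#' @param split fractions summing to 1.
#' @param seed integer.
#' @return list of integer index vectors `train`, `val`, `test`.
#' @export
split_indices <- function(n, split, seed) {
  perm <- with_preserved_rng({ set.seed(seed); sample.int(n) })
  n_train <- floor(split[1] * n)
  n_val <- floor(split[2] * n)
  if (n_train < 1 || n_val < 1 || n_train + n_val >= n)
    stop("split leaves an empty train/validation/test set at n = ", n)
  list(train = sort(perm[seq_len(n_train)]),
       val = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[(n_train + n_val + 1):n]))
}

subset_dataset <- function(dataset, idx) {
  dataset$records <- dataset$records[idx]
  dataset
}

# Split every site, pool standardization moments for shared features over the
# sites' TRAIN records (moment triples only), standardize + impute all splits,
# and pack tensors.
prepare_federation_data <- function(datasets, manifest, config) {
  shared_dyn <- shared_features(manifest, kind = "dynamic_numeric")
  splits <- lapply(datasets, function(ds)
    split_indices(n_patients(ds), config$split,
                  derive_seed(config$seed, paste0("split:", ds$institution_id))))
  names(splits) <- vapply(datasets, `[[`, "", "institution_id")

  train_moments <- lapply(seq_along(datasets), function(k)
    compute_local_moments(subset_dataset(datasets[[k]], splits[[k]]$train)))
  site_feats <- lapply(datasets, `[[`, "dynamic_features")

  metadata <- vector("list", length(datasets))
  for (k in seq_along(datasets)) {
    md <- list()
    for (f in site_feats[[k]]) {
      contributors <- if (f %in% shared_dyn) {
        which(vapply(site_feats, function(sf) f %in% sf, logical(1)))
      } else k
      md[f] <- merge_moments(lapply(train_moments[contributors],
                                    function(m) m[f]))[f]
    }
    metadata[[k]] <- structure(md, class = "standardization_metadata")
  }

  # the remaining-LOS regression target is standardized with the same pooled
  # moment-sharing pattern (count/sum/sumsq over the LOS sites' train
  # records), so its loss is commensurate with the cross-entropy term and one
  # shared scale serves every federation mode; predictions are reported on
  # the original day scale
  los_cnt <- 0; los_sum <- 0; los_ssq <- 0
  sites <- vector("list", length(datasets))
  for (k in seq_along(datasets)) {
    ds <- datasets[[k]]
    std <- standardize(ds, metadata[[k]])
    fill <- compute_demographic_fill(subset_dataset(std, splits[[k]]$train))
    std <- impute(std, fill)
    tensors <- prepare_site_tensors(std)
    sp <- splits[[k]]
    if (ds$task %in% c("los", "both")) {
      y <- tensors$Y_los[sp$train, ]
      y <- y[!is.na(y)]
      los_cnt <- los_cnt + length(y)
      los_sum <- los_sum + sum(y)
      los_ssq <- los_ssq + sum(y^2)
    }
    sites[[k]] <- list(institution_id = ds$institution_id, task = ds$task,
                       tensors = tensors, split = sp,
                       metadata = metadata[[k]], demographic_fill = fill)
  }
  if (los_cnt > 0) {
    center <- los_sum / los_cnt
    scale <- sqrt(max(los_ssq / los_cnt - center^2, 0))
    if (scale < 1e-8) scale <- 1
    for (k in seq_along(sites)) {
      sites[[k]]$tensors$los_center <- center
      sites[[k]]$tensors$los_scale <- scale
    }
  }
  names(sites) <- names(splits)
  sites
}

site_minibatches <- function(idx, batch_size, seed) {
  perm <- with_preserved_rng({ set.seed(seed); sample(idx) })
  split(perm, ceiling(seq_along(perm) / batch_size))
}

# Validation metric, higher-is-better: AUPRC for classification sites,
# negative MSE for regression-only sites. A degenerate single-class
# validation split falls back to negative loss.
validation_metric <- function(model, tensors, idx) {
  out <- site_forward(model, tensors, idx, train = FALSE)
  if (!is.null(out$p_mort)) {
    m <- tryCatch(auprc(out$p_mort, out$y_mort), error = function(e) NA_real_)
    if (is.na(m)) m <- -out$loss
    list(metric = m, auprc = m, loss = out$loss)
  } else {
    list(metric = -out$loss_reg, auprc = NA_real_, loss = out$loss)
  }
}

#' One local update in FedAvg mode
#'
#' Runs `local_epochs` epochs of mini-batch AdamW/Adam on the site's own loss
#' and returns the updated flat parameters and the sample count `M_n` as a
#' validated [client_message()].
#'
#' @param model a `site_model` (its shared keys must equal the current global
#'   snapshot; the caller guards this).
#' @param tensors training tensors from [prepare_site_tensors()].
#' @param idx training patient indices.
#' @param opt_state optimizer state (updated in place via return value).
#' @param config a [fed_config()].
#' @param epoch current epoch (seeds the shuffle/dropout streams).
#' @return list(message, model, opt_state, train_loss).
#' @export
local_update <- function(model, tensors, idx, opt_state, config, epoch) {
  total_loss <- 0; n_batches <- 0
  for (e in seq_len(config$local_epochs)) {
    batches <- site_minibatches(
      idx, config$batch_size,
      derive_seed(config$seed, sprintf("shuffle:%s:%d:%d",
                                       model$institution_id, epoch, e)))
    for (b in seq_along(batches)) {
      out <- site_forward(
        model, tensors, batches[[b]], train = TRUE, dropout = config$dropout,
        compute_grads = TRUE,
        rng_seed = derive_seed(config$seed, sprintf("dropout:%s:%d:%d:%d",
                                                    model$institution_id,
                                                    epoch, e, b)))
      st <- adam_step(flatten_site_params(model), out$grads, opt_state,
                      lr = config$lr, weight_decay = config$weight_decay,
                      variant = config$optimizer)
      model <- set_site_params(model, st$params)
      opt_state <- st$state
      total_loss <- total_loss + out$loss
      n_batches <- n_batches + 1
    }
  }
  msg <- client_message(model$institution_id, "params",
                        flatten_site_params(model), length(idx))
  list(message = msg, model = model, opt_state = opt_state,
       train_loss = total_loss / max(n_batches, 1))
}

#' One gradient-accumulation round (multitask collaborative training)
#'
#' Each site evaluates the loss gradient of one mini-batch at the current
#' shared snapshot with unused parameters frozen and masked (keys for features
#' it does not record are absent from its message), the server accumulates the
#' shared-key gradients and takes a single optimizer step, and each site steps
#' its private keys locally with its own optimizer state.
#'
#' @param state round state: list with `models`, `opt_states` (per site),
#'   `server_params` (flat shared snapshot), `server_opt`, `shared_keys`.
#' @param sites per-site data from the training pipeline.
#' @param batches list per site of the mini-batch indices for this round.
#' @param config a [fed_config()].
#' @param round_seed_tag string tag seeding this round's dropout streams.
#' @param aggregate logical: FALSE reproduces isolated training in the same
#'   code path.
#' @return updated `state`, plus `train_loss` per site.
#' @export
multitask_round <- function(state, sites, batches, config, round_seed_tag,
                            aggregate = TRUE) {
  G <- list()
  losses <- stats::setNames(numeric(length(sites)), names(sites))
  for (id in names(sites)) {
    model <- state$models[[id]]
    own <- flatten_site_params(model)
    if (aggregate) {
      # protocol guard: the site's shared keys must match the server snapshot
      for (key in intersect(names(state$server_params), names(own))) {
        if (!isTRUE(all.equal(own[[key]], state$server_params[[key]],
                              tolerance = 0)))
          stop("stale client '", id, "': shared snapshot mismatch on ", key)
      }
    }
    if (is.null(batches[[id]])) next
    out <- site_forward(
      model, sites[[id]]$tensors, batches[[id]], train = TRUE,
      dropout = config$dropout, compute_grads = TRUE,
      rng_seed = derive_seed(config$seed,
                             paste0("dropout:", id, ":", round_seed_tag)))
    losses[id] <- out$loss
    gshared <- out$grads[intersect(names(out$grads), state$shared_keys)]
    gpriv <- out$grads[setdiff(names(out$grads), state$shared_keys)]
    if (aggregate) {
      msg <- client_message(id, "gradient", gshared, length(batches[[id]]))
      for (key in names(msg$payload))
        G[[key]] <- if (is.null(G[[key]])) msg$payload[[key]]
                    else G[[key]] + msg$payload[[key]]
    } else {
      gpriv <- c(gpriv, gshared)  # isolated: sites own all their keys
    }
    st <- adam_step(own, gpriv, state$opt_states[[id]], lr = config$lr,
                    weight_decay = config$weight_decay,
                    variant = config$optimizer)
    state$models[[id]] <- set_site_params(model, st$params)
    state$opt_states[[id]] <- st$state
  }
  if (aggregate && length(G)) {
    st <- adam_step(state$server_params, G, state$server_opt, lr = config$lr,
                    weight_decay = config$weight_decay,
                    variant = config$optimizer)
    state$server_params <- st$params
    state$server_opt <- st$state
    for (id in names(sites))
      state$models[[id]] <- set_site_params(state$models[[id]],
                                            state$server_params)
  }
  state$train_loss <- losses
  state
}

#' Federated multi-institution training
#'
#' Full pipeline: per-site 70/10/20 split, pooled moment standardization of
#' shared features, mean imputation, model initialization with bit-identical
#' shared channels, then round-based training in the configured mode with
#' per-site early stopping on the validation metric (AUPRC for classification
#' sites, negative MSE for regression-only sites). Every site's returned
#' model is its best-validation snapshot.
#'
#' @param datasets list of raw [institution_dataset()] objects.
#' @param manifest the federation [feature_manifest()].
#' @param config a [fed_config()].
#' @return list of class `fed_result`: `models` (per site), `history`
#'   (data.frame, one row per epoch x site), `sites` (tensors, splits,
#'   metadata), `partition`, `config`, `manifest`.
#' @export
train_federated <- function(datasets, manifest, config = fed_config()) {
  sites <- prepare_federation_data(datasets, manifest, config)
  ids <- names(sites)
  part <- partition_parameters(manifest)
  centralized <- config$mode == "centralized"
  aggregate <- config$mode == "federated" && length(ids) > 1

  if (centralized) {
    tasks <- vapply(sites, `[[`, "", "task")
    central_task <- if (all(tasks == "mortality")) "mortality"
                    else if (all(tasks == "los")) "los" else "both"
    central <- init_site_model(manifest, "central", central_task,
                               h = config$h, seed = config$seed)
    models <- stats::setNames(rep(list(central), length(ids)), ids)
  } else {
    models <- stats::setNames(lapply(ids, function(id)
      init_site_model(manifest, id, sites[[id]]$task, h = config$h,
                      seed = config$seed)), ids)
  }
  opt_states <- lapply(models, function(m) adam_init(flatten_site_params(m)))
  server_params <- fedavg_aggregate(
    lapply(models, flatten_site_params),
    vapply(sites, function(s) length(s$split$train), numeric(1)),
    part$shared_keys)
  server_opt <- adam_init(server_params)
  if (config$mode == "federated")
    for (id in ids) models[[id]] <- set_site_params(models[[id]], server_params)

  best <- lapply(ids, function(id) list(metric = -Inf, params = NULL, epoch = 0))
  names(best) <- ids
  wait <- stats::setNames(rep(0L, length(ids)), ids)
  stopped <- stats::setNames(rep(FALSE, length(ids)), ids)
  history <- list()

  for (epoch in seq_len(config$epochs)) {
    active <- ids[!stopped]
    if (!length(active)) break
    train_losses <- stats::setNames(rep(NA_real_, length(ids)), ids)

    if (centralized) {
      # single model; all sites' mini-batches interleaved in one shuffled
      # schedule, approximating SGD over the pooled cohort
      m <- models[[1]]; ost <- opt_states[[1]]
      schedule <- list()
      for (id in ids) {
        batches <- site_minibatches(
          sites[[id]]$split$train, config$batch_size,
          derive_seed(config$seed, sprintf("shuffle:%s:%d", id, epoch)))
        for (b in seq_along(batches))
          schedule[[length(schedule) + 1]] <-
            list(id = id, b = b, idx = batches[[b]])
      }
      ord <- with_preserved_rng({
        set.seed(derive_seed(config$seed, sprintf("schedule:%d", epoch)))
        sample.int(length(schedule))
      })
      tl <- stats::setNames(rep(0, length(ids)), ids)
      nb <- stats::setNames(rep(0, length(ids)), ids)
      for (item in schedule[ord]) {
        m$task <- sites[[item$id]]$task
        out <- site_forward(m, sites[[item$id]]$tensors, item$idx,
                            train = TRUE, dropout = config$dropout,
                            compute_grads = TRUE,
                            rng_seed = derive_seed(config$seed,
                              sprintf("dropout:%s:%d:%d", item$id, epoch,
                                      item$b)))
        st <- adam_step(flatten_site_params(m), out$grads, ost,
                        lr = config$lr, weight_decay = config$weight_decay,
                        variant = config$optimizer)
        m <- set_site_params(m, st$params); ost <- st$state
        tl[item$id] <- tl[item$id] + out$loss
        nb[item$id] <- nb[item$id] + 1
      }
      train_losses[ids] <- tl / pmax(nb, 1)
      m$task <- central_task
      for (id in ids) { models[[id]] <- m; models[[id]]$task <- sites[[id]]$task }
      opt_states <- stats::setNames(rep(list(ost), length(ids)), ids)
    } else if (config$fed_mode == "fedavg") {
      msgs <- list(); counts <- numeric(0)
      for (id in active) {
        up <- local_update(models[[id]], sites[[id]]$tensors,
                           sites[[id]]$split$train, opt_states[[id]],
                           config, epoch)
        models[[id]] <- up$model
        opt_states[[id]] <- up$opt_state
        train_losses[id] <- up$train_loss
        msgs[[id]] <- up$message
      }
      if (config$mode == "federated") {
        agg <- fedavg_aggregate(lapply(msgs, `[[`, "payload"),
                                vapply(msgs, `[[`, numeric(1), "n_samples"),
                                part$shared_keys)
        for (id in active) models[[id]] <- set_site_params(models[[id]], agg)
      }
    } else {  # accum
      batch_lists <- lapply(active, function(id)
        site_minibatches(sites[[id]]$split$train, config$batch_size,
                         derive_seed(config$seed,
                                     sprintf("shuffle:%s:%d", id, epoch))))
      names(batch_lists) <- active
      n_rounds <- max(vapply(batch_lists, length, integer(1)))
      state <- list(models = models[active],
                    opt_states = opt_states[active],
                    server_params = server_params, server_opt = server_opt,
                    shared_keys = part$shared_keys)
      acc_loss <- stats::setNames(rep(0, length(active)), active)
      for (r in seq_len(n_rounds)) {
        batches <- lapply(active, function(id) {
          bl <- batch_lists[[id]]
          bl[[(r - 1) %% length(bl) + 1]]
        })
        names(batches) <- active
        state <- multitask_round(state, sites[active], batches, config,
                                 sprintf("%d:%d", epoch, r),
                                 aggregate = config$mode == "federated")
        acc_loss <- acc_loss + state$train_loss
      }
      models[active] <- state$models
      opt_states[active] <- state$opt_states
      server_params <- state$server_params
      server_opt <- state$server_opt
      train_losses[active] <- acc_loss / n_rounds
    }

    for (id in ids) {
      vm <- validation_metric(models[[id]], sites[[id]]$tensors,
                              sites[[id]]$split$val)
      improved <- !stopped[id] && vm$metric > best[[id]]$metric + 1e-12
      if (improved) {
        best[[id]] <- list(metric = vm$metric,
                           params = flatten_site_params(models[[id]]),
                           epoch = epoch)
        wait[id] <- 0L
      } else if (!stopped[id]) {
        wait[id] <- wait[id] + 1L
        if (wait[id] >= config$patience) stopped[id] <- TRUE
      }
      history[[length(history) + 1]] <- data.frame(
        epoch = epoch, site = id, train_loss = train_losses[id],
        val_metric = vm$metric, val_auprc = vm$auprc, val_loss = vm$loss,
        stopped = stopped[id], row.names = NULL)
    }
  }

  for (id in ids)
    if (!is.null(best[[id]]$params))
      models[[id]] <- set_site_params(models[[id]], best[[id]]$params)

  if (config$finetune_epochs > 0) {
    for (id in ids) {
      ost <- adam_init(flatten_site_params(models[[id]]))
      for (e in seq_len(config$finetune_epochs)) {
        up <- local_update(models[[id]], sites[[id]]$tensors,
                           sites[[id]]$split$train, ost, config,
                           epoch = 100000L + e)
        models[[id]] <- up$model; ost <- up$opt_state
      }
    }
  }

  structure(list(models = models, history = do.call(rbind, history),
                 sites = sites, partition = part, config = config,
                 manifest = manifest,
                 best = lapply(best, function(b) b[c("metric", "epoch")])),
            class = "fed_result")
}

#' Test-set predictions and metrics for every site
#'
#' @param result a `fed_result` from [train_federated()].
#' @param split which split to evaluate (`"test"`, `"val"`, `"train"`).
#' @return named list per site: scores, labels, LOS predictions and point
#'   metrics.
#' @export
evaluate_sites <- function(result, split = "test") {
  out <- list()
  for (id in names(result$sites)) {
    site <- result$sites[[id]]
    idx <- site$split[[split]]
    fw <- site_forward(result$models[[id]], site$tensors, idx, train = FALSE)
    metrics <- list()
    if (!is.null(fw$p_mort)) {
      metrics$auroc <- tryCatch(auroc(fw$p_mort, fw$y_mort),
                                error = function(e) NA_real_)
      metrics$auprc <- tryCatch(auprc(fw$p_mort, fw$y_mort),
                                error = function(e) NA_real_)
    }
    if (!is.null(fw$los_pred)) {
      ok <- !is.na(fw$los_true)
      metrics$mse <- mse_loss(fw$los_pred[ok], fw$los_true[ok])
      metrics$rmse <- sqrt(metrics$mse)
      metrics$mae <- mae_loss(fw$los_pred[ok], fw$los_true[ok])
    }
    out[[id]] <- list(p_mort = fw$p_mort, y_mort = fw$y_mort,
                      los_pred = fw$los_pred, los_true = fw$los_true,
                      alpha_last = fw$alpha_last, metrics = metrics)
  }
  out
}

#' Write a per-round history log as JSONL
#' @param history the `history` data.frame of a `fed_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_history_jsonl <- function(history, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(history)))
    writeLines(as.character(jsonlite::toJSON(as.list(history[i, ]),
                                             auto_unbox = TRUE, digits = NA,
                                             na = "null")), con)
  invisible(path)
}

#' Read a JSONL history log back
#' @param path JSONL file.
#' @return data.frame.
#' @export
read_history_jsonl <- function(path) {
  rows <- lapply(readLines(path, encoding = "UTF-8"), function(l) {
    rec <- jsonlite::fromJSON(l)
    rec[vapply(rec, is.null, logical(1))] <- NA
    as.data.frame(rec)
  })
  do.call(rbind, rows)
}

#' Save / load a model checkpoint
#'
#' Versioned JSON archive of the flat keyed parameters of every site model
#' plus the shared/private partition tags and the training configuration.
#'
#' @param result a `fed_result`.
#' @param path checkpoint file.
#' @return `path` invisibly / the reloaded `fed_result` skeleton (models,
#'   partition, config, manifest — no data tensors).
#' @export
save_checkpoint <- function(result, path) {
  enc <- function(a) list(dim = if (is.matrix(a)) dim(a) else length(a),
                          data = as.numeric(a))
  sites <- lapply(names(result$models), function(id) {
    m <- result$models[[id]]
    list(institution_id = id, task = m$task, h = m$h,
         params = lapply(flatten_site_params(m), enc))
  })
  names(sites) <- names(result$models)
  obj <- list(format = "fedprog-checkpoint", version = 1L,
              config = unclass(result$config),
              shared_keys = result$partition$shared_keys,
              manifest = list(recorded_by = result$manifest$recorded_by,
                              feature_kind = as.list(result$manifest$feature_kind)),
              sites = sites)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$format, "fedprog-checkpoint"))
    stop("not a fedprog checkpoint: ", path)
  kinds <- unlist(obj$manifest$feature_kind)
  manifest <- feature_manifest(
    lapply(obj$manifest$recorded_by, function(v) unlist(v)), kinds)
  dec <- function(e) {
    d <- unlist(e$dim)
    v <- as.numeric(unlist(e$data))
    if (length(d) == 2) matrix(v, d[1], d[2]) else v
  }
  models <- lapply(obj$sites, function(s) {
    m <- init_site_model(manifest, s$institution_id, s$task, h = s$h, seed = 1L)
    set_site_params(m, lapply(s$params, dec))
  })
  names(models) <- names(obj$sites)
  cfg <- obj$config
  list(models = models, manifest = manifest,
       shared_keys = unlist(obj$shared_keys), config = cfg)
}
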