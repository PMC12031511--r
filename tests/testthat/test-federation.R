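# Parameter partition, aggregation, round protocol, training engine.

test_that("partition: identical manifests share all channels, heads stay private", {
  mf <- feature_manifest(
    recorded_by = list(A = c("age", "f1", "f2"), B = c("age", "f1", "f2")),
    kinds = c(age = "static_demographic", f1 = "dynamic_numeric",
              f2 = "dynamic_numeric"))
  part <- partition_parameters(mf)
  expect_true(all(paste0("channel.f1.", fedprog:::GATE_NAMES) %in% part$shared_keys))
  expect_true(all(paste0("channel.f2.", fedprog:::GATE_NAMES) %in% part$shared_keys))
  expect_true("demographic.W_base" %in% part$shared_keys)
  expect_true(all(grepl("^(recalib|head)\\.",
                        setdiff(unlist(part$private_keys), part$shared_keys))))
  expect_false(any(grepl("^head\\.", part$shared_keys)))
})

test_that("partition: fully disjoint manifests warn that no transfer is possible", {
  mf <- feature_manifest(
    recorded_by = list(A = c("ageA", "f1"), B = c("ageB", "f2")),
    kinds = c(ageA = "static_demographic", ageB = "static_demographic",
              f1 = "dynamic_numeric", f2 = "dynamic_numeric"))
  expect_warning(part <- partition_parameters(mf), "no cross-site transfer")
  expect_false(any(grepl("^channel\\.", part$shared_keys)))
})

test_that("partition of the default study config: 20 shared and 12 private channels", {
  mf <- cohort_manifest(default_study_config())
  part <- partition_parameters(mf)
  shared_ch <- unique(sub("^channel\\.(.*)\\.[A-Za-z]+$", "\\1",
                          grep("^channel\\.", part$shared_keys, value = TRUE)))
  expect_length(shared_ch, 8 + 3 * 4)
  priv_ch <- unique(sub("^channel\\.(.*)\\.[A-Za-z]+$", "\\1",
                        grep("^channel\\.", unlist(part$private_keys),
                             value = TRUE)))
  expect_length(priv_ch, 3 * 4)
})

test_that("fedavg aggregation is the count-weighted mean over contributing sites", {
  pa <- list(w = matrix(1.0, 2, 2))
  pb <- list(w = matrix(3.0, 2, 2))
  # equal counts -> plain mean
  expect_equal(fedavg_aggregate(list(pa, pb), c(5, 5))$w, matrix(2, 2, 2))
  # counts 1 and 3 -> (1*1 + 3*3)/4 = 2.5
  expect_equal(fedavg_aggregate(list(pa, pb), c(1, 3))$w, matrix(2.5, 2, 2))
  # single client is the identity
  expect_identical(fedavg_aggregate(list(pa), 7)$w, pa$w)
  # a key absent at one site averages over the sites that hold it
  pc <- list(w = matrix(3.0, 2, 2), only_b = 10)
  agg <- fedavg_aggregate(list(pa, pc), c(1, 3))
  expect_equal(agg$only_b, 10)
  expect_error(fedavg_aggregate(list(), numeric(0)), "at least one")
})

test_that("client messages carry only parameter tensors and counts", {
  payload <- list("channel.f1.Wz" = rnorm(4), "head.W_cla" = rnorm(4))
  msg <- client_message("A", "params", payload, 12)
  expect_s3_class(msg, "client_message")
  expect_error(client_message("A", "params",
                              c(payload, list(patient_ids = c("p1", "p2"))), 12),
               "naming scheme")
  expect_error(client_message("A", "records", payload, 12), "payload type")
  bad <- payload; bad[["head.W_cla"]] <- c("a", "b")
  expect_error(client_message("A", "params", bad, 12), "numeric")
})

test_that("zero learning rate is a null update", {
  co <- tiny_cohort(seed = 41)
  cfg <- fed_config(h = 4, seed = 4, lr = 0, weight_decay = 0,
                    split = c(0.6, 0.2, 0.2), batch_size = 8)
  sites <- fedprog:::prepare_federation_data(co$datasets, co$manifest, cfg)
  id <- names(sites)[1]
  model <- init_site_model(co$manifest, id, sites[[id]]$task, h = 4, seed = 4)
  before <- flatten_site_params(model)
  up <- local_update(model, sites[[id]]$tensors, sites[[id]]$split$train,
                     adam_init(before), cfg, epoch = 1)
  after <- flatten_site_params(up$model)
  for (key in names(before)) expect_equal(after[[key]], before[[key]])
  expect_equal(up$message$n_samples, length(sites[[id]]$split$train))
})

test_that("freeze-and-mask: a site's gradient message has no keys for unrecorded features", {
  co <- tiny_cohort(seed = 43)
  cfg <- fed_config(h = 4, seed = 2, split = c(0.6, 0.2, 0.2))
  sites <- fedprog:::prepare_federation_data(co$datasets, co$manifest, cfg)
  mf <- co$manifest
  for (id in names(sites)) {
    model <- init_site_model(mf, id, sites[[id]]$task, h = 4, seed = 2)
    out <- site_forward(model, sites[[id]]$tensors,
                        sites[[id]]$split$train[1:4], compute_grads = TRUE)
    absent <- setdiff(canonical_dynamic_features(mf),
                      institution_dynamic_features(mf, id))
    for (f in absent)
      expect_length(grep(paste0("channel.", f, "."), names(out$grads),
                         fixed = TRUE), 0)
  }
})

test_that("a batch gradient is the mean of single-record gradients", {
  co <- tiny_cohort(seed = 45)
  cfg <- fed_config(h = 4, seed = 3, split = c(0.6, 0.2, 0.2))
  sites <- fedprog:::prepare_federation_data(co$datasets, co$manifest, cfg)
  id <- names(sites)[2]  # classification-only site: loss is a mean over patients
  model <- init_site_model(co$manifest, id, sites[[id]]$task, h = 4, seed = 3)
  pair <- sites[[id]]$split$train[1:2]
  g_both <- site_forward(model, sites[[id]]$tensors, pair,
                         compute_grads = TRUE)$grads
  g1 <- site_forward(model, sites[[id]]$tensors, pair[1],
                     compute_grads = TRUE)$grads
  g2 <- site_forward(model, sites[[id]]$tensors, pair[2],
                     compute_grads = TRUE)$grads
  for (key in names(g_both))
    expect_equal(g_both[[key]], (g1[[key]] + g2[[key]]) / 2, tolerance = 1e-6)
})

test_that("one accumulation round sums site gradients like the pooled-loss calculus", {
  # two sites with identical manifests/tasks; full-batch round: the server's
  # accumulated gradient must equal the sum of independently computed
  # full-batch site gradients
  cfgc <- cohort_config(2, c(12, 12), 2, 0, 0, T_range = c(2, 3),
                        tasks = c("mortality", "mortality"), seed = 51)
  co <- generate_cohorts(cfgc)
  cfg <- fed_config(fed_mode = "accum", h = 3, seed = 7, dropout = 0,
                    split = c(0.6, 0.2, 0.2), batch_size = 100)
  sites <- fedprog:::prepare_federation_data(co$datasets, co$manifest, cfg)
  part <- partition_parameters(co$manifest)
  models <- lapply(names(sites), function(id)
    init_site_model(co$manifest, id, "mortality", h = 3, seed = 7))
  names(models) <- names(sites)
  expected <- list()
  for (id in names(sites)) {
    g <- site_forward(models[[id]], sites[[id]]$tensors,
                      sites[[id]]$split$train, compute_grads = TRUE)$grads
    for (key in intersect(names(g), part$shared_keys))
      expected[[key]] <- if (is.null(expected[[key]])) g[[key]]
                         else expected[[key]] + g[[key]]
  }
  # run the round with an lr-0 server to read off the accumulated gradient
  # indirectly: instead re-run with captured gradients via the same entry
  state <- list(models = models,
                opt_states = lapply(models, function(m)
                  adam_init(flatten_site_params(m))),
                server_params = fedavg_aggregate(
                  lapply(models, flatten_site_params),
                  vapply(sites, function(s) length(s$split$train), numeric(1)),
                  part$shared_keys),
                server_opt = NULL, shared_keys = part$shared_keys)
  state$server_opt <- adam_init(state$server_params)
  state$models <- lapply(state$models, function(m)
    set_site_params(m, state$server_params))
  batches <- lapply(sites, function(s) s$split$train)
  new_state <- multitask_round(state, sites, batches, cfg, "1:1")
  # the Adam first moment after one step from zero is (1 - beta1) * G
  for (key in names(expected))
    expect_equal(new_state$server_opt$m[[key]] / (1 - 0.9), expected[[key]],
                 tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("stale clients are rejected in accumulation rounds", {
  cfgc <- cohort_config(2, c(10, 10), 2, 0, 0, T_range = c(2, 3),
                        tasks = c("mortality", "mortality"), seed = 53)
  co <- generate_cohorts(cfgc)
  cfg <- fed_config(fed_mode = "accum", h = 3, seed = 7,
                    split = c(0.6, 0.2, 0.2))
  sites <- fedprog:::prepare_federation_data(co$datasets, co$manifest, cfg)
  part <- partition_parameters(co$manifest)
  models <- lapply(names(sites), function(id)
    init_site_model(co$manifest, id, "mortality", h = 3, seed = 7))
  names(models) <- names(sites)
  state <- list(models = models,
                opt_states = lapply(models, function(m)
                  adam_init(flatten_site_params(m))),
                server_params = fedavg_aggregate(
                  lapply(models, flatten_site_params), c(1, 1),
                  part$shared_keys),
                server_opt = NULL, shared_keys = part$shared_keys)
  state$server_opt <- adam_init(state$server_params)
  state$models <- lapply(state$models, function(m)
    set_site_params(m, state$server_params))
  key <- part$shared_keys[1]
  stale <- flatten_site_params(state$models[[1]])
  stale[[key]] <- stale[[key]] + 1
  state$models[[1]] <- set_site_params(state$models[[1]], stale)
  expect_error(multitask_round(state, sites,
                               lapply(sites, function(s) s$split$train),
                               cfg, "1:1"),
               "stale client")
})

test_that("federated training with one site is bit-identical to isolated training", {
  co <- tiny_cohort(seed = 61)
  mf <- co$manifest
  for (fm in c("fedavg", "accum")) {
    cfg_f <- fed_config(mode = "federated", fed_mode = fm, epochs = 3,
                        h = 4, batch_size = 8, seed = 11,
                        split = c(0.6, 0.2, 0.2))
    cfg_i <- fed_config(mode = "isolated", fed_mode = fm, epochs = 3,
                        h = 4, batch_size = 8, seed = 11,
                        split = c(0.6, 0.2, 0.2))
    rf <- train_federated(co$datasets[1], mf, cfg_f)
    ri <- train_federated(co$datasets[1], mf, cfg_i)
    expect_identical(flatten_site_params(rf$models[[1]]),
                     flatten_site_params(ri$models[[1]]))
    expect_identical(rf$history$train_loss, ri$history$train_loss)
  }
})

test_that("training is deterministic under a fixed seed", {
  co <- tiny_cohort(seed = 63)
  cfg <- fed_config(epochs = 2, h = 4, batch_size = 8, seed = 13,
                    split = c(0.6, 0.2, 0.2))
  a <- train_federated(co$datasets, co$manifest, cfg)
  b <- train_federated(co$datasets, co$manifest, cfg)
  expect_identical(a$history, b$history)
  expect_identical(flatten_site_params(a$models[[1]]),
                   flatten_site_params(b$models[[1]]))
})

test_that("after aggregation every site copy of every shared key is identical", {
  co <- tiny_cohort(seed = 65)
  cfg <- fed_config(mode = "federated", epochs = 2, h = 4, batch_size = 8,
                    seed = 17, split = c(0.6, 0.2, 0.2))
  res <- train_federated(co$datasets, co$manifest, cfg)
  # restore the end-of-training (pre-best-restore) check by re-running one
  # round by hand: run 1 epoch, no early stop, and compare copies directly
  cfg1 <- fed_config(mode = "federated", epochs = 1, h = 4, batch_size = 8,
                     seed = 17, patience = 5, split = c(0.6, 0.2, 0.2))
  r1 <- train_federated(co$datasets, co$manifest, cfg1)
  pa <- flatten_site_params(r1$models[[1]])
  pb <- flatten_site_params(r1$models[[2]])
  for (key in intersect(r1$partition$shared_keys,
                        intersect(names(pa), names(pb))))
    expect_identical(pa[[key]], pb[[key]])
})

test_that("early stopping fires after the configured patience", {
  co <- tiny_cohort(seed = 67)
  cfg <- fed_config(epochs = 30, patience = 3, h = 4, batch_size = 8,
                    seed = 19, lr = 0, split = c(0.6, 0.2, 0.2))
  # with lr 0 the validation metric never improves after epoch 1
  res <- train_federated(co$datasets, co$manifest, cfg)
  h1 <- res$history[res$history$site == res$history$site[1], ]
  expect_equal(max(h1$epoch), 1 + 3)
})

test_that("history logs round-trip through JSONL", {
  co <- tiny_cohort(seed = 69)
  cfg <- fed_config(epochs = 2, h = 4, batch_size = 8, seed = 23,
                    split = c(0.6, 0.2, 0.2))
  res <- train_federated(co$datasets, co$manifest, cfg)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_history_jsonl(res$history, path)
  back <- read_history_jsonl(path)
  expect_equal(nrow(back), nrow(res$history))
  expect_equal(back$train_loss, res$history$train_loss, tolerance = 1e-12)
  expect_equal(back$site, res$history$site)
})

test_that("checkpoints round-trip parameters exactly", {
  co <- tiny_cohort(seed = 71)
  cfg <- fed_config(epochs = 1, h = 4, batch_size = 8, seed = 29,
                    split = c(0.6, 0.2, 0.2))
  res <- train_federated(co$datasets, co$manifest, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(res, path)
  back <- load_checkpoint(path)
  for (id in names(res$models)) {
    a <- flatten_site_params(res$models[[id]])
    b <- flatten_site_params(back$models[[id]])
    for (key in names(a)) expect_equal(b[[key]], a[[key]], ignore_attr = TRUE)
  }
})
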