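# On-disk institution dataset format and moment-sharing standardization.

make_two_patient_dataset <- function() {
  feats <- c("crp", "urea")
  r1 <- patient_record(
    "p1",
    dynamics = matrix(c(1, 2, 3, 4, NA, 6), 2, 3, byrow = TRUE,
                      dimnames = list(feats, NULL)),
    observed_mask = matrix(c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE), 2, 3,
                           byrow = TRUE, dimnames = list(feats, NULL)),
    demographics = c(age = 71, gender = 0),
    mortality = 1, los_remaining = c(5, 4, 3))
  r2 <- patient_record(
    "p2",
    dynamics = matrix(c(0.5, NA, 2.5, 1.5), 2, 2, byrow = TRUE,
                      dimnames = list(feats, NULL)),
    observed_mask = matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2, byrow = TRUE,
                           dimnames = list(feats, NULL)),
    demographics = c(age = 45, gender = 1),
    mortality = 0, los_remaining = c(9, 8))
  institution_dataset("siteA", "both", feats, c("age", "gender"),
                      list(r1, r2))
}

test_that("write then load is the identity on every field including masks", {
  ds <- make_two_patient_dataset()
  dir <- withr::local_tempdir()
  write_institution_dataset(ds, dir)
  back <- load_institution_dataset(dir)
  expect_identical(back$institution_id, ds$institution_id)
  expect_identical(back$task, ds$task)
  expect_identical(back$dynamic_features, ds$dynamic_features)
  for (i in seq_along(ds$records)) {
    a <- ds$records[[i]]; b <- back$records[[i]]
    expect_identical(b$patient_id, a$patient_id)
    expect_equal(b$dynamics, a$dynamics)
    expect_identical(b$observed_mask, a$observed_mask)
    expect_equal(b$demographics, a$demographics)
    expect_equal(b$mortality, a$mortality)
    expect_equal(b$los_remaining, a$los_remaining)
  }
})

test_that("an empty value cell yields exactly one FALSE mask entry", {
  dir <- withr::local_tempdir()
  writeLines(c("patient_id,time_index,feature,value",
               "p1,0,f1,1.0", "p1,1,f1,", "p1,2,f1,3.0",
               "p1,0,f2,4.0", "p1,1,f2,5.0", "p1,2,f2,6.0"),
             file.path(dir, "timeseries.csv"))
  writeLines(c("patient_id,age", "p1,50"), file.path(dir, "demographics.csv"))
  writeLines(c("patient_id,time_index,mortality,los_remaining",
               "p1,0,0,", "p1,1,0,", "p1,2,0,"),
             file.path(dir, "labels.csv"))
  jsonlite::write_json(list(
    institution_id = "s", task = "mortality",
    features = list(list(name = "f1", kind = "dynamic_numeric"),
                    list(name = "f2", kind = "dynamic_numeric"),
                    list(name = "age", kind = "static_demographic"))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  ds <- load_institution_dataset(dir)
  expect_equal(sum(!ds$records[[1]]$observed_mask), 1)
  expect_false(ds$records[[1]]$observed_mask["f1", 2])
  expect_equal(ds$records[[1]]$los_remaining, NULL)
})

test_that("loader errors name the failure: missing files, unknown features, bad numbers", {
  ds <- make_two_patient_dataset()
  dir <- withr::local_tempdir()
  write_institution_dataset(ds, dir)
  file.remove(file.path(dir, "labels.csv"))
  expect_error(load_institution_dataset(dir), "labels.csv")

  dir2 <- withr::local_tempdir()
  write_institution_dataset(ds, dir2)
  ts <- readLines(file.path(dir2, "timeseries.csv"))
  writeLines(c(ts, "p1,0,not_in_manifest,1.0"), file.path(dir2, "timeseries.csv"))
  expect_error(load_institution_dataset(dir2), "absent from manifest")

  dir3 <- withr::local_tempdir()
  write_institution_dataset(ds, dir3)
  ts <- readLines(file.path(dir3, "timeseries.csv"))
  ts[2] <- sub("^(p1,0,[a-z]+,).*$", "\\1abc", ts[2])
  writeLines(ts, file.path(dir3, "timeseries.csv"))
  expect_error(load_institution_dataset(dir3), "non-numeric.*row 1")
})

test_that("local moments count observed entries only and error on unrecorded features", {
  ds <- make_two_patient_dataset()
  m <- compute_local_moments(ds, "crp")
  # crp observed values: 1, 2, 3 (p1) and 0.5 (p2, second time masked)
  expect_equal(m$crp$count, 4)
  expect_equal(m$crp$sum, 6.5)
  expect_equal(m$crp$sumsq, 1 + 4 + 9 + 0.25)
  expect_error(compute_local_moments(ds, "not_recorded"), "not recorded")
})

test_that("merged moments equal pooled moments: worked example and random partitions", {
  # sites holding {1,3} and {5}: pooled mean 3, population std sqrt(8/3)
  mA <- list(x = list(count = 2, sum = 4, sumsq = 10))
  mB <- list(x = list(count = 1, sum = 5, sumsq = 25))
  md <- merge_moments(list(mA, mB))
  expect_equal(md$x$mean, 3.0)
  expect_equal(md$x$std, sqrt(8 / 3), tolerance = 1e-10)
  expect_equal(md$x$std, 1.63299, tolerance = 1e-4)

  # one site is the identity; two identical sites keep mean/std
  expect_equal(merge_moments(list(mA))$x$mean, 2)
  same <- merge_moments(list(mA, mA))
  expect_equal(same$x$mean, 2)
  expect_equal(same$x$std, merge_moments(list(mA))$x$std)

  # random partitions over <= 5 sites match the direct pooled oracle,
  # in any merge order
  set.seed(42)
  for (trial in 1:20) {
    vals <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 3))
    k <- sample(1:5, 1)
    part <- split(vals, sample(k, length(vals), replace = TRUE))
    sets <- lapply(part, function(v)
      list(x = list(count = length(v), sum = sum(v), sumsq = sum(v^2))))
    oracle <- pooled_moments_oracle(vals)
    for (ord in list(seq_along(sets), rev(seq_along(sets)))) {
      md <- merge_moments(sets[ord])
      expect_equal(md$x$mean, oracle$mean, tolerance = 1e-10)
      expect_equal(md$x$std, oracle$std, tolerance = 1e-10)
    }
  }
})

test_that("zero-count features are degenerate and pass through standardization", {
  md <- merge_moments(list(list(x = list(count = 0, sum = 0, sumsq = 0))))
  expect_true(md$x$degenerate)
  feats <- "x"
  r <- patient_record("p", matrix(c(7, 8), 1, 2, dimnames = list(feats, NULL)),
                      matrix(TRUE, 1, 2, dimnames = list(feats, NULL)),
                      c(age = 50), mortality = 0)
  ds <- institution_dataset("s", "mortality", feats, "age", list(r))
  out <- standardize(ds, md)
  expect_equal(out$records[[1]]$dynamics["x", ], c(7, 8))
})

test_that("standardization centers and scales observed values by the pooled metadata", {
  md <- merge_moments(list(list(x = list(count = 3, sum = 9, sumsq = 35))))
  # values {1,3,5}: mean 3, population std sqrt(8/3)
  r <- patient_record("p", matrix(c(1, 3, 5), 1, 3, dimnames = list("x", NULL)),
                      matrix(TRUE, 1, 3, dimnames = list("x", NULL)),
                      c(age = 50), mortality = 0)
  ds <- institution_dataset("s", "mortality", "x", "age", list(r))
  out <- standardize(ds, md)
  expect_equal(out$records[[1]]$dynamics["x", ],
               c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(unname(out$records[[1]]$dynamics["x", 2]), 0)  # value at the mean
  expect_true(out$standardized)
})

test_that("imputation fills standardized missing cells with 0 and keeps the mask", {
  feats <- "x"
  r <- patient_record("p", matrix(c(1, NA, 5), 1, 3, dimnames = list(feats, NULL)),
                      matrix(c(TRUE, FALSE, TRUE), 1, 3,
                             dimnames = list(feats, NULL)),
                      c(age = NA, gender = NA), mortality = 0)
  ds <- institution_dataset("s", "mortality", feats, c("age", "gender"), list(r))
  md <- merge_moments(list(compute_local_moments(ds)))
  out <- impute(standardize(ds, md),
                demographic_fill = list(age = 60, gender = 1))
  expect_equal(unname(out$records[[1]]$dynamics["x", 2]), 0)
  expect_false(out$records[[1]]$observed_mask["x", 2])  # missingness retained
  expect_equal(unname(out$records[[1]]$demographics["gender"]), 1)  # mode fill
  # a fully observed record passes through unchanged
  r2 <- make_two_patient_dataset()
  md2 <- lapply(r2$dynamic_features, function(f)
    list(count = 1, mean = 0, std = 1, degenerate = FALSE))
  names(md2) <- r2$dynamic_features
  std2 <- r2; std2$standardized <- TRUE
  out2 <- impute(std2)
  expect_equal(out2$records[[1]]$dynamics[, 1], r2$records[[1]]$dynamics[, 1])
})

test_that("moments exchange file round-trips and manifests expose the shared/private split", {
  m <- list(crp = list(count = 4, sum = 6.5, sumsq = 14.25),
            urea = list(count = 2, sum = 1, sumsq = 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_moments(m, path)
  expect_equal(read_moments(path), m)

  mf <- tiny_manifest()
  expect_setequal(shared_features(mf), c("age", "gender", "crp"))
  expect_setequal(private_features(mf, "A"), c("urea", "hr"))
  expect_setequal(pairwise_shared(mf, "A", "B"), c("age", "gender", "crp"))
  expect_error(feature_manifest(list(A = character(0)),
                                c(x = "dynamic_numeric")), "non-empty")
})
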