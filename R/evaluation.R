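#' Ranking metrics for imbalanced outcomes
#'
#' `auroc()` is the Mann-Whitney pair statistic
#' `P(score_pos > score_neg) + 0.5 P(tie)`, computed from mid-ranks.
#' `auprc()` is the average-precision formulation: the mean, over positives,
#' of the precision at each positive's rank, with tied scores sharing the
#' average precision of their tie group (equivalent to averaging over random
#' tie orders); under complete ties it equals the prevalence. AUPRC is the
#' headline metric throughout because the outcomes are imbalanced.
#'
#' @param scores numeric risk scores (higher = more likely positive).
#' @param labels 0/1 labels.
#' @return value in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("auroc is undefined when only one class is present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' @rdname auroc
#' @export
auprc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("auprc is undefined without positives")
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]; s <- scores[o]
  n <- length(y)
  # one threshold per distinct score: tied scores enter together, so under
  # complete ties the curve is a single step and AP equals the prevalence
  last_of_group <- c(s[-n] != s[-1], TRUE)
  tp <- cumsum(y)[last_of_group]
  pred_pos <- seq_len(n)[last_of_group]
  prec <- tp / pred_pos
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * prec)
}

#' Bootstrap mean/std report over the test set
#'
#' Resamples the test set with replacement `B` times, recomputes each metric
#' per replicate, and reports mean and sample standard deviation (`ddof = 1`).
#' Replicates that draw a single class are redrawn (documented behaviour, so
#' AUROC/AUPRC stay defined).
#'
#' @param scores,labels classification inputs (either may be `NULL` when only
#'   regression is evaluated).
#' @param los_pred,los_true regression inputs (optional).
#' @param B number of bootstrap replicates (default 10).
#' @param seed integer seed for resampling.
#' @return object of class `eval_report`: per metric, `point`, `replicates`,
#'   `mean`, `std`.
#' @export
bootstrap_report <- function(scores = NULL, labels = NULL,
                             los_pred = NULL, los_true = NULL,
                             B = 10L, seed = 1L) {
  if (B < 2) warning("std over ", B, " replicate(s) reported as 0")
  metrics <- list()
  add <- function(name, point, reps)
    metrics[[name]] <<- list(point = point, replicates = reps,
                             mean = mean(reps),
                             std = if (length(reps) > 1) stats::sd(reps) else 0)
  resample_sets <- NULL
  if (!is.null(scores)) {
    if (length(unique(labels)) < 2)
      stop("bootstrap of ranking metrics is undefined with a single class")
    n <- length(scores)
    resample_sets <- with_preserved_rng({
      set.seed(seed)
      lapply(seq_len(B), function(b) {
        for (try in 1:10000) {
          idx <- sample.int(n, n, replace = TRUE)
          if (length(unique(labels[idx])) == 2) return(idx)
        }
        stop("could not draw a two-class bootstrap resample")
      })
    })
    add("auroc", auroc(scores, labels),
        vapply(resample_sets, function(i) auroc(scores[i], labels[i]), numeric(1)))
    add("auprc", auprc(scores, labels),
        vapply(resample_sets, function(i) auprc(scores[i], labels[i]), numeric(1)))
  }
  if (!is.null(los_pred)) {
    ok <- !is.na(los_true)
    lp <- los_pred[ok]; lt <- los_true[ok]
    m <- length(lp)
    reg_sets <- with_preserved_rng({
      set.seed(derive_seed(seed, "reg"))
      lapply(seq_len(B), function(b) sample.int(m, m, replace = TRUE))
    })
    add("mse", mse_loss(lp, lt),
        vapply(reg_sets, function(i) mse_loss(lp[i], lt[i]), numeric(1)))
    add("rmse", rmse_loss(lp, lt),
        vapply(reg_sets, function(i) rmse_loss(lp[i], lt[i]), numeric(1)))
    add("mae", mae_loss(lp, lt),
        vapply(reg_sets, function(i) mae_loss(lp[i], lt[i]), numeric(1)))
  }
  structure(list(metrics = metrics, B = B, seed = seed,
                 resample_indices = resample_sets),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> B =", x$B, "\n")
  for (nm in names(x$metrics)) {
    m <- x$metrics[[nm]]
    scale <- if (nm %in% c("auroc", "auprc")) 100 else 1
    cat(sprintf("  %-6s %6.2f (bootstrap %6.2f +/- %.2f)\n",
                nm, m$point * scale, m$mean * scale, m$std * scale))
  }
  invisible(x)
}

#' Compare two methods' bootstrap replicates
#'
#' Two-sided t-test on the replicate vectors: paired (same resample indices
#' for both methods) or Welch unpaired. Identical replicate vectors, or zero
#' variance in both with equal means, give p = 1 by convention.
#'
#' @param replicates_a,replicates_b numeric replicate vectors.
#' @param paired logical.
#' @return list `p_value`, `direction` (`"a>b"`, `"b>a"`, `"equal"`),
#'   `mean_a`, `mean_b`.
#' @export
compare_methods <- function(replicates_a, replicates_b, paired = TRUE) {
  if (paired && length(replicates_a) != length(replicates_b))
    stop("paired comparison needs equal replicate counts")
  ma <- mean(replicates_a); mb <- mean(replicates_b)
  direction <- if (ma > mb) "a>b" else if (mb > ma) "b>a" else "equal"
  degenerate <- if (paired) stats::var(replicates_a - replicates_b) == 0
                else stats::var(replicates_a) == 0 && stats::var(replicates_b) == 0
  p <- if (degenerate) {
    if (ma == mb) 1 else 0
  } else {
    stats::t.test(replicates_a, replicates_b, paired = paired)$p.value
  }
  list(p_value = p, direction = direction, mean_a = ma, mean_b = mb)
}

#' Serialize evaluation reports
#'
#' JSON retains every replicate; the CSV summary prints `mean +/- std` to two
#' decimals with classification metrics scaled by 100 for readability.
#'
#' @param reports named list (method or site -> `eval_report`).
#' @param json_path,csv_path output paths (either may be `NULL`).
#' @return invisibly, the summary data.frame.
#' @export
write_eval_reports <- function(reports, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    obj <- lapply(reports, function(r)
      list(B = r$B, seed = r$seed,
           metrics = lapply(r$metrics, function(m)
             list(point = m$point, mean = m$mean, std = m$std,
                  replicates = m$replicates))))
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)
  }
  rows <- list()
  for (nm in names(reports)) {
    r <- reports[[nm]]
    for (mt in names(r$metrics)) {
      m <- r$metrics[[mt]]
      scale <- if (mt %in% c("auroc", "auprc")) 100 else 1
      rows[[length(rows) + 1]] <- data.frame(
        method = nm, metric = mt,
        summary = sprintf("%.2f ± %.2f", m$mean * scale, m$std * scale))
    }
  }
  df <- do.call(rbind, rows)
  if (!is.null(csv_path)) write_csv_plain(df, csv_path)
  invisible(df)
}
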