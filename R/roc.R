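# Replicate-level ROC evaluation by threshold averaging.

check_replicates <- function(replicates) {
  if (!length(replicates)) stopf("at least one replicate is required")
  lapply(seq_along(replicates), function(i) {
    r <- replicates[[i]]
    s <- r$scores
    causal <- r$causal
    if (is.null(s) || is.null(causal))
      stopf("replicate %d lacks `scores`/`causal`", i)
    if (!is.logical(causal)) {
      idx <- as.integer(causal)
      causal <- rep(FALSE, length(s)); causal[idx] <- TRUE
    }
    if (length(causal) != length(s))
      stopf("replicate %d: causal flags and scores differ in length", i)
    if (!any(causal)) stopf("replicate %d has no causal SNP flagged", i)
    if (all(causal)) stopf("replicate %d has no non-causal SNP", i)
    if (any(!is.finite(s))) stopf("replicate %d has non-finite scores", i)
    list(scores = as.numeric(s), causal = causal)
  })
}

# Fraction of scores at-or-above each threshold, for one sorted score vector.
frac_at_or_above <- function(scores_sorted, thresholds) {
  n <- length(scores_sorted)
  (n - findInterval(thresholds, scores_sorted, left.open = TRUE)) / n
}

roc_rates <- function(replicates, thresholds) {
  tpr <- vapply(replicates, function(r)
    frac_at_or_above(sort(r$scores[r$causal]), thresholds),
    numeric(length(thresholds)))
  fpr <- vapply(replicates, function(r)
    frac_at_or_above(sort(r$scores[!r$causal]), thresholds),
    numeric(length(thresholds)))
  list(tpr = matrix(tpr, nrow = length(thresholds)),
       fpr = matrix(fpr, nrow = length(thresholds)))
}

#' Threshold-averaged ROC curve across simulated replicates
#'
#' Builds a single ROC curve from many replicate datasets by threshold
#' averaging: a common grid of score thresholds is laid over all replicates
#' and, at each threshold, the true-positive rate (fraction of causal SNPs
#' scoring at or above it) and false-positive rate (fraction of non-causal
#' SNPs at or above it) are averaged across replicates. With a single causal
#' SNP per replicate the mean TPR at a threshold is the fraction of
#' replicates whose causal SNP would be retained.
#'
#' @param replicates List of replicates, each a list with `scores` (per-SNP
#'   filtering statistic) and `causal` (logical flags or causal index).
#' @param n_thresholds Size of the threshold grid, taken as quantiles of the
#'   pooled score distribution (default 512); the grid is augmented with
#'   `+Inf`/`-Inf` so every curve starts at (0, 0) and ends at (1, 1).
#' @param thresholds Optional explicit threshold grid overriding the pooled
#'   quantiles.
#' @return An object of class `roc_curve`: list with `thresholds`
#'   (descending), `mean_fpr`, `mean_tpr`, `n_replicates`.
#' @export
roc_threshold_average <- function(replicates, n_thresholds = 512,
                                  thresholds = NULL) {
  reps <- check_replicates(replicates)
  if (is.null(thresholds)) {
    pooled <- unlist(lapply(reps, `[[`, "scores"))
    thresholds <- stats::quantile(pooled,
                                  probs = seq(0, 1, length.out = n_thresholds),
                                  type = 7, names = FALSE)
  }
  thresholds <- c(Inf, sort(unique(thresholds), decreasing = TRUE), -Inf)
  rates <- roc_rates(reps, thresholds)
  structure(list(thresholds = thresholds,
                 mean_fpr = rowMeans(rates$fpr),
                 mean_tpr = rowMeans(rates$tpr),
                 n_replicates = length(reps)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d thresholds averaged over %d replicates; AUC %.4f\n",
              length(x$thresholds), x$n_replicates, auc(x)))
  invisible(x)
}

#' Area under a threshold-averaged ROC curve
#'
#' Trapezoid-rule area under the (mean FPR, mean TPR) curve.
#'
#' @param curve A `roc_curve`, or a list/data.frame with `mean_fpr` and
#'   `mean_tpr`.
#' @return Area in `[0, 1]`.
#' @export
auc <- function(curve) {
  fpr <- curve$mean_fpr; tpr <- curve$mean_tpr
  if (length(fpr) < 2L) stopf("at least two curve points are required")
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
}

#' Bootstrap distribution of the AUC over replicates
#'
#' Resamples replicates with replacement and recomputes the
#' threshold-averaged AUC, giving the Monte-Carlo uncertainty of an AUC
#' estimate (per-threshold rates are computed once and only re-averaged, so
#' resampling is cheap).
#'
#' @inheritParams roc_threshold_average
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed for the resampling.
#' @return Numeric vector of `n_boot` bootstrap AUC values.
#' @export
roc_auc_bootstrap <- function(replicates, n_boot = 1000, n_thresholds = 512,
                              seed = 1L) {
  reps <- check_replicates(replicates)
  pooled <- unlist(lapply(reps, `[[`, "scores"))
  thresholds <- c(Inf, sort(unique(
    stats::quantile(pooled, probs = seq(0, 1, length.out = n_thresholds),
                    type = 7, names = FALSE)), decreasing = TRUE), -Inf)
  rates <- roc_rates(reps, thresholds)
  R <- length(reps)
  with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(R, R, replace = TRUE)
      auc(list(mean_fpr = rowMeans(rates$fpr[, idx, drop = FALSE]),
               mean_tpr = rowMeans(rates$tpr[, idx, drop = FALSE])))
    }, numeric(1))
  })
}

#' SNPs retained when fixing the mean true-positive rate
#'
#' Finds the most stringent score threshold at which the mean TPR across
#' replicates (the fraction of replicates whose causal SNP is retained)
#' reaches `target_tpr`, and summarizes how many SNPs each replicate retains
#' at that threshold. Optionally, a second statistic's retained sets are
#' intersected with the first's, replicate by replicate.
#'
#' @inheritParams roc_threshold_average
#' @param target_tpr Target mean TPR in (0, 1].
#' @param secondary Optional list parallel to `replicates` giving a second
#'   score vector per replicate (same SNP order); its own threshold is
#'   found for the same target and per-replicate intersection counts are
#'   reported.
#' @return A list of class `retention_summary` with `threshold`,
#'   `achieved_tpr`, `mean_retained`, `sd_retained`, `retained` (per
#'   replicate), and when `secondary` is given, `secondary_threshold`,
#'   `mean_intersection`, `sd_intersection`.
#' @export
retained_at_tpr <- function(replicates, target_tpr, secondary = NULL) {
  check_scalar_number(target_tpr, "target_tpr", 0, 1, open_lower = TRUE)
  reps <- check_replicates(replicates)

  pick_threshold <- function(reps) {
    cand <- sort(unique(unlist(lapply(reps, `[[`, "scores"))),
                 decreasing = TRUE)
    tpr <- rowMeans(matrix(vapply(reps, function(r)
      frac_at_or_above(sort(r$scores[r$causal]), cand),
      numeric(length(cand))), nrow = length(cand)))
    hit <- which(tpr >= target_tpr)
    if (!length(hit))
      stopf("target mean TPR %.3g is unreachable (max achievable %.3g)",
            target_tpr, max(tpr))
    list(threshold = cand[hit[1L]], achieved = tpr[hit[1L]])
  }

  thr <- pick_threshold(reps)
  retained <- vapply(reps, function(r) sum(r$scores >= thr$threshold),
                     integer(1))
  out <- list(threshold = thr$threshold, achieved_tpr = thr$achieved,
              target_tpr = target_tpr,
              mean_retained = mean(retained),
              sd_retained = stats::sd(retained), retained = retained)

  if (!is.null(secondary)) {
    reps2 <- lapply(seq_along(reps), function(i)
      list(scores = as.numeric(secondary[[i]]), causal = reps[[i]]$causal))
    reps2 <- check_replicates(reps2)
    thr2 <- pick_threshold(reps2)
    inter <- vapply(seq_along(reps), function(i)
      sum(reps[[i]]$scores >= thr$threshold &
            reps2[[i]]$scores >= thr2$threshold), integer(1))
    out$secondary_threshold <- thr2$threshold
    out$mean_intersection <- mean(inter)
    out$sd_intersection <- stats::sd(inter)
    out$intersection <- inter
  }
  structure(out, class = "retention_summary")
}

#' @export
print.retention_summary <- function(x, ...) {
  cat(sprintf("<retention_summary> TPR %.2f at threshold %.4g: mean retained %.1f (SD %.1f)\n",
              x$target_tpr, x$threshold, x$mean_retained, x$sd_retained))
  invisible(x)
}

#' Train/test protocol for the empirical-Bayes prior variance
#'
#' Quantifies overfitting from estimating the prior variance on the same
#' data it scores: for each disjoint train/test pair of replicate datasets,
#' the surrogate prior variance is estimated on the training member and used
#' to compute Wakefield Bayes factors in the test member ("train-test"),
#' compared with estimating and applying it in the test member itself
#' ("same-data"). Both score sets are reduced to threshold-averaged ROC
#' curves.
#'
#' @param pairs List of pairs; each pair is a list with `train` and `test`
#'   (summary data frames from [summarize_all()] over the same SNP set) and
#'   `causal` (causal flags or index for the test member).
#' @param p_percent Top-percentage passed to [surrogate_w_eb()].
#' @param n_thresholds Threshold-grid size for the ROC curves.
#' @return List with `same_data` and `train_test` (`roc_curve`s),
#'   `auc_same`, `auc_train_test`, and the per-pair prior variances
#'   `w_train`, `w_test`.
#' @export
train_test_web <- function(pairs, p_percent = 30, n_thresholds = 512) {
  if (!length(pairs)) stopf("at least one train/test pair is required")
  same <- vector("list", length(pairs))
  tt <- vector("list", length(pairs))
  w_train <- w_test <- numeric(length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    if (is.null(p$train) || is.null(p$test) || is.null(p$causal))
      stopf("pair %d lacks train/test/causal", i)
    if (!identical(p$train$snp_id, p$test$snp_id))
      stopf("pair %d: train and test cover different SNP sets", i)
    tr <- p$train[p$train$flag == "ok", , drop = FALSE]
    te <- p$test[p$test$flag == "ok", , drop = FALSE]
    w_train[i] <- surrogate_w_eb(tr, p_percent)$W
    w_test[i] <- surrogate_w_eb(te, p_percent)$W
    causal <- p$causal
    if (!is.logical(causal)) {
      idx <- as.integer(causal)
      causal <- p$test$snp_id %in% p$test$snp_id[idx]
    }
    causal <- causal[p$test$flag == "ok"]
    same[[i]] <- list(scores = wakefield_bf(te$beta_hat, te$V, w_test[i],
                                            log = TRUE), causal = causal)
    tt[[i]] <- list(scores = wakefield_bf(te$beta_hat, te$V, w_train[i],
                                          log = TRUE), causal = causal)
  }
  curve_same <- roc_threshold_average(same, n_thresholds)
  curve_tt <- roc_threshold_average(tt, n_thresholds)
  list(same_data = curve_same, train_test = curve_tt,
       auc_same = auc(curve_same), auc_train_test = auc(curve_tt),
       w_train = w_train, w_test = w_test)
}
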