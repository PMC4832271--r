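# Threshold-averaged ROC curves, AUC, retention summaries and the
# train/test protocol.

test_that("a single replicate reduces to the empirical ROC", {
  set.seed(40)
  scores <- rnorm(50)
  causal <- seq_len(50) %in% sample(50, 5)
  oracle <- empirical_roc(scores, causal)
  curve <- roc_threshold_average(list(list(scores = scores, causal = causal)),
                                 thresholds = unique(scores))
  expect_equal(curve$thresholds, oracle$thresholds)
  expect_equal(curve$mean_tpr, oracle$tpr)
  expect_equal(curve$mean_fpr, oracle$fpr)
})

test_that("curves are monotone and anchored at (0,0) and (1,1)", {
  set.seed(41)
  reps <- lapply(1:20, function(i)
    list(scores = rnorm(40), causal = seq_len(40) == sample(40, 1)))
  curve <- roc_threshold_average(reps, n_thresholds = 64)
  expect_equal(curve$mean_fpr[1], 0)
  expect_equal(curve$mean_tpr[1], 0)
  expect_equal(curve$mean_fpr[length(curve$mean_fpr)], 1)
  expect_equal(curve$mean_tpr[length(curve$mean_tpr)], 1)
  expect_true(all(diff(curve$mean_fpr) >= 0))
  expect_true(all(diff(curve$mean_tpr) >= 0))
  expect_true(all(curve$mean_fpr >= 0 & curve$mean_fpr <= 1))
})

test_that("a perfect statistic reaches TPR 1 at any positive FPR", {
  reps <- lapply(1:10, function(i) {
    s <- runif(30); s[7] <- 2    # causal SNP always on top
    list(scores = s, causal = seq_len(30) == 7)
  })
  curve <- roc_threshold_average(reps, n_thresholds = 128)
  expect_true(all(curve$mean_tpr[curve$mean_fpr > 0] == 1))
  expect_equal(auc(curve), 1)
})

test_that("uninformative scores give AUC about one half", {
  set.seed(42)
  reps <- lapply(1:200, function(i)
    list(scores = runif(100), causal = seq_len(100) == sample(100, 1)))
  a <- auc(roc_threshold_average(reps, n_thresholds = 256))
  expect_equal(a, 0.5, tolerance = 0.07)
})

test_that("AUC is exact on hand-built curves and matches a sort oracle", {
  expect_equal(auc(list(mean_fpr = c(0, 0.5, 1), mean_tpr = c(0, 0.5, 1))), 0.5)
  expect_equal(auc(list(mean_fpr = c(0, 0, 1), mean_tpr = c(0, 1, 1))), 1)
  expect_error(auc(list(mean_fpr = 0.5, mean_tpr = 0.5)), "two curve points")
  set.seed(43)
  scores <- rnorm(200); causal <- seq_len(200) %in% sample(200, 20)
  curve <- roc_threshold_average(list(list(scores = scores, causal = causal)),
                                 thresholds = unique(scores))
  # Wilcoxon identity for the empirical ROC area (ties handled as 1/2)
  w <- mean(outer(scores[causal], scores[!causal],
                  function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(auc(curve), w, tolerance = 1e-12)
})

test_that("replicates without a causal or non-causal SNP are rejected by name", {
  good <- list(scores = 1:5, causal = c(TRUE, rep(FALSE, 4)))
  bad <- list(scores = 1:5, causal = rep(FALSE, 5))
  expect_error(roc_threshold_average(list(good, bad)), "replicate 2")
  expect_error(roc_threshold_average(list()), "at least one replicate")
})

test_that("retention at a target TPR matches hand counting", {
  # 4 replicates, 10 SNPs; causal scores 9,9,9,2 -> threshold 9 gives TPR 0.75
  reps <- lapply(1:4, function(i) {
    s <- c(if (i < 4) 9 else 2, seq(0.1, 0.9, length.out = 9))
    list(scores = s, causal = c(TRUE, rep(FALSE, 9)))
  })
  out <- retained_at_tpr(reps, 0.75)
  expect_equal(out$threshold, 9)
  expect_equal(out$achieved_tpr, 0.75)
  expect_equal(out$mean_retained, 0.75)     # only the causal SNP scores >= 9
  out9 <- retained_at_tpr(reps, 0.9)        # needs the lax threshold 2
  expect_equal(out9$threshold, 2)
  expect_equal(out9$achieved_tpr, 1)
  expect_error(retained_at_tpr(reps, 1.5), "target_tpr")
})

test_that("a perfect statistic retains about one SNP; a constant retains all", {
  reps <- lapply(1:20, function(i) {
    s <- runif(40); s[3] <- 2
    list(scores = s, causal = seq_len(40) == 3)
  })
  out <- retained_at_tpr(reps, 0.9)
  expect_equal(out$mean_retained, 1)
  const <- lapply(1:5, function(i)
    list(scores = rep(1, 40), causal = seq_len(40) == 3))
  expect_equal(retained_at_tpr(const, 0.9)$mean_retained, 40)
})

test_that("intersection counts use both statistics' own thresholds", {
  reps <- lapply(1:3, function(i) {
    s <- seq(1, 10); list(scores = s, causal = seq_len(10) == 10)
  })
  secondary <- lapply(1:3, function(i) seq(10, 1))  # reversed ordering
  out <- retained_at_tpr(reps, 0.9, secondary = secondary)
  # primary retains only the causal SNP; the secondary statistic ranks it
  # last, so its own threshold must drop to the minimum and retain all 10,
  # leaving an intersection of exactly the causal SNP
  expect_equal(out$mean_retained, 1)
  expect_equal(out$secondary_threshold, 1)
  expect_equal(out$mean_intersection, 1)
})

test_that("identical train and test datasets give identical curves", {
  sim <- sim_summaries(n_snps = 25, n_cases = 300, n_controls = 300,
                       or = 1.8, causal = 12, seed = 50)
  pair <- list(train = sim$summaries, test = sim$summaries, causal = 12L)
  out <- train_test_web(list(pair, pair))
  expect_identical(out$same_data, out$train_test)
  expect_equal(out$w_train, out$w_test)
  bad <- list(train = sim$summaries[-1, ], test = sim$summaries, causal = 12L)
  expect_error(train_test_web(list(bad)), "different SNP sets")
})

test_that("null data yield chance-level AUC for both protocols", {
  pairs <- lapply(1:20, function(i) {
    a <- sim_summaries(n_snps = 25, n_cases = 150, n_controls = 150, or = 1.0,
                       causal = 12, seed = 200 + 2 * i)
    b <- sim_summaries(n_snps = 25, n_cases = 150, n_controls = 150, or = 1.0,
                       causal = 12, seed = 201 + 2 * i)
    list(train = a$summaries, test = b$summaries, causal = 12L)
  })
  out <- train_test_web(pairs, n_thresholds = 128)
  expect_equal(out$auc_same, 0.5, tolerance = 0.2)
  expect_equal(out$auc_train_test, 0.5, tolerance = 0.2)
})

test_that("no material overfitting with a strong effect at large n", {
  pairs <- lapply(1:15, function(i) {
    a <- sim_summaries(n_snps = 25, n_cases = 500, n_controls = 500, or = 1.6,
                       causal = 12, seed = 300 + 2 * i)
    b <- sim_summaries(n_snps = 25, n_cases = 500, n_controls = 500, or = 1.6,
                       causal = 12, seed = 301 + 2 * i)
    list(train = a$summaries, test = b$summaries, causal = 12L)
  })
  out <- train_test_web(pairs, n_thresholds = 128)
  expect_gt(out$auc_same, 0.8)
  expect_equal(out$auc_same, out$auc_train_test, tolerance = 0.05)
})

test_that("bootstrap AUCs concentrate around the point estimate", {
  set.seed(44)
  reps <- lapply(1:50, function(i) {
    s <- rnorm(30); s[5] <- s[5] + 2
    list(scores = s, causal = seq_len(30) == 5)
  })
  a <- auc(roc_threshold_average(reps, n_thresholds = 128))
  boot <- roc_auc_bootstrap(reps, n_boot = 300, n_thresholds = 128, seed = 9)
  expect_length(boot, 300)
  expect_lt(abs(mean(boot) - a), 3 * sd(boot))
  expect_gt(sd(boot), 0)
})
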