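# Independent oracles and fixture builders used across the suite.

# Newton-Raphson maximization of the aggregated-counts logistic likelihood,
# written without glm so it can serve as an independent oracle for the IRLS
# path. counts_* are counts of subjects with dosage 0, 1, 2.
newton_logistic_counts <- function(counts_case, counts_ctrl, tol = 1e-12) {
  x <- c(0, 1, 2, 0, 1, 2)
  y <- c(1, 1, 1, 0, 0, 0)
  w <- c(counts_case, counts_ctrl)
  theta <- c(0, 0)
  for (i in 1:100) {
    eta <- theta[1] + theta[2] * x
    mu <- 1 / (1 + exp(-eta))
    score <- c(sum(w * (y - mu)), sum(w * x * (y - mu)))
    v <- w * mu * (1 - mu)
    info <- matrix(c(sum(v), sum(v * x), sum(v * x), sum(v * x^2)), 2)
    step <- solve(info, score)
    theta <- theta + step
    if (max(abs(step)) < tol) break
  }
  eta <- theta[1] + theta[2] * x
  mu <- 1 / (1 + exp(-eta))
  v <- w * mu * (1 - mu)
  info <- matrix(c(sum(v), sum(v * x), sum(v * x), sum(v * x^2)), 2)
  list(beta_hat = theta[2], V = solve(info)[2, 2],
       loglik = sum(w * (y * log(mu) + (1 - y) * log(1 - mu))))
}

# Expand an aggregated 2x3 genotype table into subject-level vectors.
expand_counts <- function(counts_case, counts_ctrl) {
  list(dosages = c(rep(0:2, counts_case), rep(0:2, counts_ctrl)),
       phenotype = rep(c(1, 0), c(sum(counts_case), sum(counts_ctrl))))
}

# Sort-based empirical ROC for a single replicate: points at every distinct
# threshold under the at-or-above retention convention.
empirical_roc <- function(scores, causal) {
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(th, function(t) mean(scores[causal] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(scores[!causal] >= t), numeric(1))
  list(thresholds = th, fpr = fpr, tpr = tpr)
}

# Small simulated dataset + summaries used by several tests.
sim_summaries <- function(n_snps = 30, n_cases = 400, n_controls = 400,
                          or = 1.5, maf = 0.2, causal = 10, seed = 7,
                          ld = 0.5, n_haplotypes = 600) {
  panel <- make_haplotype_panel(n_haplotypes, n_snps,
                                maf_sampler = function(n) runif(n, 0.05, 0.5),
                                ld_profile = ld, seed = seed)
  ds <- simulate_case_control(panel, causal, or, n_cases, n_controls,
                              prevalence = 0.05, seed = seed + 1)
  list(panel = panel, dataset = ds, summaries = summarize_all(ds))
}

# Hand-built association summary table (usable SNPs, distinct likelihoods).
toy_summaries <- function(beta, V, loglik, snp_id = NULL) {
  data.frame(snp_id = snp_id %||% sprintf("s%02d", seq_along(beta)),
             position = seq_along(beta), maf = 0.2, beta_hat = beta,
             se = sqrt(V), V = V, z_sq = beta^2 / V, loglik = loglik,
             n_used = 100L, flag = "ok", stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
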