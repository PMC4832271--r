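#' Wakefield approximate Bayes factor
#'
#' Closed-form asymptotic Bayes factor for a single SNP under a Gaussian
#' N(0, W) prior on the log odds ratio and asymptotic normality
#' \eqn{\hat\beta_1 \sim N(\beta_1, V)}:
#' \deqn{WBF = \sqrt{V/(V+W)} \exp\{\hat\beta_1^2 W / (2 V (V+W))\}.}
#' The value is oriented as evidence for association (H1 : H0), i.e. the
#' reciprocal of Wakefield's original ratio, so larger is more associated.
#' Equivalently it is the Gaussian marginal-likelihood ratio
#' `dnorm(beta_hat, 0, sqrt(V+W)) / dnorm(beta_hat, 0, sqrt(V))`.
#'
#' @param beta_hat Estimated log odds ratio(s).
#' @param V Sampling variance(s) of `beta_hat`; must be > 0.
#' @param W Prior variance of the log odds ratio; must be >= 0. `W = 0`
#'   (point-mass prior at zero) gives a Bayes factor of exactly 1.
#' @param log If `TRUE`, return the log Bayes factor (numerically safe for
#'   very large evidence).
#' @return Bayes factor(s) > 0 (or their logs).
#' @export
wakefield_bf <- function(beta_hat, V, W, log = FALSE) {
  if (any(!is.finite(V)) || any(V <= 0)) stopf("`V` must be positive")
  if (any(!is.finite(W)) || any(W < 0)) stopf("`W` must be >= 0")
  lbf <- 0.5 * log(V / (V + W)) + beta_hat^2 * W / (2 * V * (V + W))
  if (log) lbf else exp(lbf)
}

#' Empirical-Bayes prior variance for the log odds ratio
#'
#' The value of the prior variance `W` that maximizes the Wakefield Bayes
#' factor viewed as a function of `W`:
#' \eqn{W_{EB} = \max(\hat\beta_1^2 - V, 0)}.
#'
#' @inheritParams wakefield_bf
#' @return `W >= 0`, vectorized over inputs.
#' @export
estimate_w_eb <- function(beta_hat, V) {
  if (any(!is.finite(V)) || any(V <= 0)) stopf("`V` must be positive")
  pmax(beta_hat^2 - V, 0)
}

#' Empirical-Bayes Wakefield Bayes factor
#'
#' The Wakefield Bayes factor evaluated at the SNP's own maximizing prior
#' variance [estimate_w_eb()]. With \eqn{z^2 = \hat\beta_1^2 / V}:
#' \deqn{BF_{EB} = z^{-1} \exp\{(z^2 - 1)/2\}} when \eqn{z^2 \ge 1}, and
#' exactly 1 otherwise (the maximizing prior collapses to a point mass).
#' Always >= 1.
#'
#' @inheritParams wakefield_bf
#' @export
bf_eb <- function(beta_hat, V, log = FALSE) {
  if (any(!is.finite(V)) || any(V <= 0)) stopf("`V` must be positive")
  z2 <- beta_hat^2 / V
  lbf <- ifelse(z2 >= 1, -0.5 * log(z2) + (z2 - 1) / 2, 0)
  if (log) lbf else exp(lbf)
}

#' Effect-size prior constructor
#'
#' Wraps a prior variance for the log odds ratio together with its
#' provenance, so that downstream output can record how `W` was obtained.
#'
#' @param W Prior variance (>= 0).
#' @param method One of `"fixed"`, `"oracle_causal"`, `"surrogate_top_p"`,
#'   `"surrogate_max"`.
#' @param ... Further provenance fields (e.g. `beta_p`, `V_m`, `p_percent`).
#' @return An object of class `effect_size_prior`.
#' @export
effect_size_prior <- function(W, method = "fixed", ...) {
  check_scalar_number(W, "W", 0, Inf)
  structure(c(list(W = W, method = method), list(...)),
            class = "effect_size_prior")
}

#' @export
print.effect_size_prior <- function(x, ...) {
  cat(sprintf("<effect_size_prior> W = %.6g (%s)\n", x$W, x$method))
  invisible(x)
}

usable_summaries <- function(summaries) {
  if (inherits(summaries, "snp_assoc_summary")) summaries <- list(summaries)
  if (is.list(summaries) && !is.data.frame(summaries)) {
    summaries <- do.call(rbind, lapply(summaries, function(s)
      data.frame(snp_id = s$snp_id, beta_hat = s$beta_hat, V = s$V,
                 loglik = s$loglik, flag = s$flag, stringsAsFactors = FALSE)))
  }
  summaries[summaries$flag == "ok", , drop = FALSE]
}

#' Surrogate empirical-Bayes prior variance from the top p% of SNPs
#'
#' Estimates the causal SNP's effect size and variance from region-wide
#' summaries: `V_m` is the median sampling variance over all usable SNPs and
#' `beta_p` is the median |log odds ratio| over the top `p_percent`% of SNPs
#' ranked by the maximized log-likelihood of their single-SNP model (the
#' causal variant is expected to sit, with its LD partners, among the most
#' associated SNPs). The prior variance is
#' `W = max(beta_p^2 - V_m, 0)`.
#'
#' The top set contains `ceiling(p_percent/100 * M)` usable SNPs;
#' likelihood ties are broken by smaller `V`, then by `snp_id`. SNPs flagged
#' monomorphic or separated are excluded from both the median `V` and the
#' top-p pool.
#'
#' @param summaries Data frame from [summarize_all()] (or a list of
#'   `snp_assoc_summary`).
#' @param p_percent Percentage of SNPs in the top set, in (0, 100];
#'   default 30.
#' @return An `effect_size_prior` with fields `beta_p`, `V_m`, `p_percent`,
#'   `n_top`, `n_usable`.
#' @export
surrogate_w_eb <- function(summaries, p_percent = 30) {
  check_scalar_number(p_percent, "p_percent", 0, 100, open_lower = TRUE)
  u <- usable_summaries(summaries)
  if (nrow(u) == 0L) stopf("no usable SNP summaries")
  V_m <- stats::median(u$V)
  ord <- order(-u$loglik, u$V, u$snp_id)
  k <- ceiling(p_percent / 100 * nrow(u))
  beta_p <- stats::median(abs(u$beta_hat[ord[seq_len(k)]]))
  effect_size_prior(max(beta_p^2 - V_m, 0), method = "surrogate_top_p",
                    p_percent = p_percent, beta_p = beta_p, V_m = V_m,
                    n_top = k, n_usable = nrow(u))
}

#' Surrogate prior variance from the top-likelihood SNP
#'
#' Variant of [surrogate_w_eb()] that uses the log odds ratio of the single
#' SNP with the largest model likelihood (`beta_max`) instead of a top-p
#' median: `W = max(beta_max^2 - V_m, 0)`. Provided for comparison runs.
#'
#' @inheritParams surrogate_w_eb
#' @return An `effect_size_prior` with fields `beta_max`, `V_m`.
#' @export
surrogate_w_max <- function(summaries) {
  u <- usable_summaries(summaries)
  if (nrow(u) == 0L) stopf("no usable SNP summaries")
  V_m <- stats::median(u$V)
  top <- order(-u$loglik, u$V, u$snp_id)[1L]
  beta_max <- u$beta_hat[top]
  effect_size_prior(max(beta_max^2 - V_m, 0), method = "surrogate_max",
                    beta_max = beta_max, V_m = V_m, n_usable = nrow(u))
}

#' Oracle prior variance from the causal SNP's own summary
#'
#' The theoretical upper-bound choice of prior variance, available only in
#' simulation where the causal SNP is known: `W = max(beta_c^2 - V_c, 0)`
#' from the causal SNP's own estimate and variance.
#'
#' @param summary A `snp_assoc_summary` (or one-row summary data frame) for
#'   the causal SNP.
#' @return An `effect_size_prior` with method `"oracle_causal"`.
#' @export
causal_w_eb <- function(summary) {
  b <- summary$beta_hat; V <- summary$V
  effect_size_prior(estimate_w_eb(b, V), method = "oracle_causal",
                    beta_c = b, V_c = V)
}
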