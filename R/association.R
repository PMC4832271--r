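#' Per-SNP univariate logistic association fit
#'
#' Fits the single-SNP logistic regression
#' \eqn{\mathrm{logit}\,P(y=1|x) = \beta_0 + \beta_1 x} of case status on
#' minor-allele dosage by iteratively reweighted least squares, returning the
#' summary consumed by every downstream Bayes-factor formula: the log odds
#' ratio estimate `beta_hat`, its sampling variance `V` (from the inverse
#' information at the MLE), the squared Wald statistic `z_sq`, the maximized
#' log-likelihood, and the sample MAF. Fractional (imputed) dosages enter the
#' score equations directly.
#'
#' Monomorphic SNPs are flagged `"monomorphic"` and carry no estimates;
#' fits escaping to `|beta_hat| > 10` (complete or quasi-complete
#' separation) are capped at sign(beta)*10 and flagged `"separated"`. Both
#' flags mark the SNP unusable for prior estimation and ranking.
#'
#' @param dosages Numeric vector of expected minor-allele counts in `[0, 2]`.
#' @param phenotype Binary vector (1 = case) of the same length; both classes
#'   must be present.
#' @param snp_id Optional identifier carried through to the summary.
#' @return An object of class `snp_assoc_summary`: list with `snp_id`,
#'   `beta_hat`, `V`, `se`, `z_sq`, `loglik`, `maf`, `n_used`, `flag`.
#' @export
fit_snp_logistic <- function(dosages, phenotype, snp_id = NA_character_) {
  if (length(dosages) != length(phenotype))
    stopf("`dosages` and `phenotype` differ in length")
  if (!all(phenotype %in% c(0, 1)))
    stopf("`phenotype` must be binary 0/1")
  if (length(unique(phenotype)) < 2L)
    stopf("both phenotype classes must be present")
  if (any(!is.finite(dosages)) || any(dosages < 0 | dosages > 2))
    stopf("dosages must be finite values in [0, 2]")

  n <- length(dosages)
  m <- mean(dosages) / 2
  maf <- min(m, 1 - m)
  out <- list(snp_id = snp_id, beta_hat = NA_real_, V = NA_real_,
              se = NA_real_, z_sq = NA_real_, loglik = NA_real_,
              maf = maf, n_used = n, flag = "ok")

  if (stats::var(dosages) == 0) {
    out$flag <- "monomorphic"
    return(structure(out, class = "snp_assoc_summary"))
  }

  X <- cbind(1, dosages)
  fit <- suppressWarnings(
    stats::glm.fit(X, phenotype, family = stats::binomial(),
                   control = list(epsilon = 1e-10, maxit = 50L)))
  mu <- pmin(pmax(fit$fitted.values, 1e-12), 1 - 1e-12)
  beta <- unname(fit$coefficients[2L])
  w <- mu * (1 - mu)
  info <- crossprod(X * sqrt(w))
  V <- unname(solve(info)[2L, 2L])

  if (!is.finite(beta) || abs(beta) > 10) {
    out$flag <- "separated"
    beta <- sign(beta) * 10
  }
  out$beta_hat <- beta
  out$V <- V
  out$se <- sqrt(V)
  out$z_sq <- beta^2 / V
  out$loglik <- sum(ifelse(phenotype == 1, log(mu), log(1 - mu)))
  structure(out, class = "snp_assoc_summary")
}

#' @export
print.snp_assoc_summary <- function(x, ...) {
  cat(sprintf("<snp_assoc_summary> %s: beta_hat=%.4g (se %.3g), MAF %.3g, flag %s\n",
              x$snp_id, x$beta_hat, x$se, x$maf, x$flag))
  invisible(x)
}

#' Summarize all SNPs of a case-control dataset
#'
#' Applies [fit_snp_logistic()] to every SNP, preserving input order.
#'
#' @param dataset A `case_control_dataset`, or a list with elements `dosages`
#'   (N x M matrix) and `phenotype`.
#' @return A data.frame with one row per SNP and columns `snp_id`,
#'   `position`, `maf`, `beta_hat`, `se`, `V`, `z_sq`, `loglik`, `n_used`,
#'   `flag`. The number of unusable (flagged) SNPs is stored in the
#'   `"n_excluded"` attribute.
#' @export
summarize_all <- function(dataset) {
  dos <- dataset$dosages
  phen <- dataset$phenotype
  if (is.null(dos) || is.null(phen) || ncol(dos) == 0L || nrow(dos) == 0L)
    stopf("empty dataset: no dosages/phenotype to summarize")
  M <- ncol(dos)
  ids <- dataset$snp_ids %||% sprintf("snp_%04d", seq_len(M))
  pos <- dataset$positions %||% rep(NA_integer_, M)

  rows <- vector("list", M)
  for (j in seq_len(M)) {
    s <- fit_snp_logistic(dos[, j], phen, snp_id = ids[j])
    rows[[j]] <- data.frame(snp_id = s$snp_id, position = pos[j],
                            maf = s$maf, beta_hat = s$beta_hat, se = s$se,
                            V = s$V, z_sq = s$z_sq, loglik = s$loglik,
                            n_used = s$n_used, flag = s$flag,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  attr(res, "n_excluded") <- sum(res$flag != "ok")
  res
}

#' Convert a printed odds ratio and confidence interval to (beta_hat, V)
#'
#' Recovers the log odds ratio estimate and its Wald variance from published
#' point and interval estimates: `beta_hat = log(or_point)` and
#' `V = (log(ci_high / ci_low) / (2 z))^2` with `z` the standard-normal
#' quantile for the interval's confidence level. This lets published summary
#' tables feed the Bayes-factor machinery directly.
#'
#' @param or_point,ci_low,ci_high Odds ratio point estimate and confidence
#'   limits, with `0 < ci_low <= or_point <= ci_high`.
#' @param level Confidence level of the interval, in (0, 1); default 0.95.
#' @return List with `beta_hat` and `V`.
#' @export
or_ci_to_summary <- function(or_point, ci_low, ci_high, level = 0.95) {
  check_scalar_number(level, "level", 0, 1, open_lower = TRUE, open_upper = TRUE)
  if (any(ci_low <= 0) || any(ci_low > or_point) || any(or_point > ci_high))
    stopf("need 0 < ci_low <= or_point <= ci_high")
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(beta_hat = log(or_point), V = (log(ci_high / ci_low) / (2 * z))^2)
}

#' Wald confidence interval on the odds-ratio scale
#'
#' Algebraic inverse of [or_ci_to_summary()].
#'
#' @param beta_hat Log odds ratio estimate.
#' @param V Its sampling variance.
#' @param level Confidence level in (0, 1).
#' @return List with `or_point`, `ci_low`, `ci_high`.
#' @export
summary_to_or_ci <- function(beta_hat, V, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(V)
  list(or_point = exp(beta_hat), ci_low = exp(beta_hat - z * se),
       ci_high = exp(beta_hat + z * se))
}
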