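#' Posterior probability of causal association
#'
#' Updates a per-SNP prior probability of causal association through a Bayes
#' factor: posterior odds = prior odds x BF, i.e.
#' \deqn{\Delta / (1 - \Delta) = \delta / (1 - \delta) \times BF.}
#' Computed in log-odds space, so the result is accurate to ~1e-12 even for
#' Bayes factors up to 1e300 and beyond (pass `log_bf` for the latter).
#'
#' @param delta Prior probability(ies) in (0, 1), exclusive: a SNP known a
#'   priori to be causal or non-causal has nothing to update.
#' @param bf Bayes factor(s) > 0; ignored when `log_bf` is given.
#' @param log_bf Optional log Bayes factor(s), numerically safe for extreme
#'   evidence.
#' @return Posterior probability(ies) `Delta` in (0, 1).
#' @export
posterior_prob <- function(delta, bf = NULL, log_bf = NULL) {
  if (any(!is.finite(delta)) || any(delta <= 0 | delta >= 1))
    stopf("`delta` must lie strictly inside (0, 1)")
  if (is.null(log_bf)) {
    if (is.null(bf)) stopf("one of `bf` or `log_bf` is required")
    if (any(!is.finite(bf)) || any(bf <= 0)) stopf("`bf` must be > 0")
    log_bf <- log(bf)
  }
  stats::plogis(stats::qlogis(delta) + log_bf)
}

#' Per-SNP posterior table from summaries, groups and priors
#'
#' Combines association summaries with group priors and an effect-size prior
#' variance into the per-SNP quantities used for ranking: log Bayes factor,
#' prior `delta`, posterior `Delta`, and the two-sided Wald p-value used for
#' comparison runs. SNPs flagged unusable get `NA` statistics and are
#' excluded by [rank_and_filter()].
#'
#' @param summaries Data frame from [summarize_all()].
#' @param group Per-SNP group labels (integer vector or
#'   `group_assignment`).
#' @param delta Either a `group_priors` object or a numeric vector of
#'   per-group prior probabilities, indexed by group label.
#' @param w An `effect_size_prior` or a single prior variance `W >= 0`.
#' @return A data.frame of class `snp_posterior_table` with columns
#'   `snp_id`, `group`, `delta`, `log_bf`, `bf`, `Delta`, `p_value`, `maf`,
#'   `flag`.
#' @export
posterior_table <- function(summaries, group, delta, w) {
  if (inherits(group, "group_assignment")) group <- group$group
  if (length(group) != nrow(summaries))
    stopf("`group` has %d labels for %d SNPs", length(group), nrow(summaries))
  dvec <- if (inherits(delta, "group_priors")) delta$delta else as.numeric(delta)
  if (any(group < 1L | group > length(dvec)))
    stopf("group labels outside 1..%d", length(dvec))
  W <- if (inherits(w, "effect_size_prior")) w$W else w
  check_scalar_number(W, "W", 0, Inf)

  ok <- summaries$flag == "ok"
  log_bf <- rep(NA_real_, nrow(summaries))
  log_bf[ok] <- wakefield_bf(summaries$beta_hat[ok], summaries$V[ok], W,
                             log = TRUE)
  d_snp <- dvec[group]
  Delta <- rep(NA_real_, nrow(summaries))
  Delta[ok] <- posterior_prob(d_snp[ok], log_bf = log_bf[ok])
  p_value <- rep(NA_real_, nrow(summaries))
  p_value[ok] <- 2 * stats::pnorm(-sqrt(summaries$z_sq[ok]))

  out <- data.frame(snp_id = summaries$snp_id, group = group, delta = d_snp,
                    log_bf = log_bf, bf = exp(log_bf), Delta = Delta,
                    p_value = p_value, maf = summaries$maf,
                    flag = summaries$flag, stringsAsFactors = FALSE)
  class(out) <- c("snp_posterior_table", "data.frame")
  out
}

#' Rank SNPs by a filtering statistic and optionally retain a subset
#'
#' Ranks SNPs in descending order of the chosen statistic (ascending for
#' p-values). Ties share the minimum ("competition") rank, displayed with a
#' leading `=` in `rank_label` as is conventional in published tables.
#' When `threshold` is given, the retained subset contains the SNPs at or
#' above the threshold (at or below, for p-values).
#'
#' @param posteriors A `snp_posterior_table` (or any data.frame containing
#'   the statistic column); rows flagged unusable are dropped.
#' @param statistic One of `"Delta"`, `"bf"`, `"p_value"` (for `"bf"` the
#'   `log_bf` column is used when present, so astronomically large Bayes
#'   factors rank correctly).
#' @param threshold Optional retention threshold on the statistic's scale.
#' @return List with `ranked` (the table sorted by rank with `rank` and
#'   `rank_label` columns) and `retained` (subset, `NULL` when no threshold
#'   was given; possibly zero rows).
#' @export
rank_and_filter <- function(posteriors,
                            statistic = c("Delta", "bf", "p_value"),
                            threshold = NULL) {
  statistic <- match.arg(statistic)
  tbl <- as.data.frame(posteriors)
  if (!is.null(tbl$flag)) tbl <- tbl[tbl$flag == "ok", , drop = FALSE]
  if (nrow(tbl) == 0L) stopf("no usable SNPs to rank")
  score_col <- if (statistic == "bf" && !is.null(tbl$log_bf)) "log_bf" else statistic
  s <- tbl[[score_col]]
  if (is.null(s)) stopf("column `%s` not found", statistic)
  if (any(!is.finite(s))) stopf("statistic values must be finite")

  key <- if (statistic == "p_value") s else -s
  rk <- rank(key, ties.method = "min")
  tied <- duplicated(key) | duplicated(key, fromLast = TRUE)
  tbl$rank <- as.integer(rk)
  tbl$rank_label <- ifelse(tied, paste0("=", rk), as.character(rk))
  ord <- order(rk, tbl$snp_id)
  ranked <- tbl[ord, , drop = FALSE]
  rownames(ranked) <- NULL

  retained <- NULL
  if (!is.null(threshold)) {
    keep <- if (statistic == "p_value") {
      ranked[[statistic]] <= threshold
    } else {
      ranked[[statistic]] >= threshold
    }
    retained <- ranked[keep, , drop = FALSE]
  }
  list(ranked = ranked, retained = retained)
}
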