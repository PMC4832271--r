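# Published iCOGS CASP8 fine-mapping example data shipped with the package.

#' Published top-ranked SNPs from the iCOGS CASP8 fine-mapping study
#'
#' Summary results for the 20 top-ranked SNPs (by posterior probability with
#' R = 5) from the iCOGS breast-cancer fine-mapping of the CASP8 region on
#' chromosome 2 (89,050 subjects, 1,733 SNPs): estimated odds ratio with 95%
#' confidence interval, sample MAF, the published Wakefield Bayes factor
#' (computed there with prior variance W = 0.0018), posterior probabilities
#' and ranks under R = 2 and R = 5, and the functional prior group. Useful
#' as a worked example: [or_ci_to_summary()] recovers (beta_hat, V) from the
#' printed intervals and [posterior_prob()] reproduces the Delta columns
#' from the group priors in [casp8_group_priors()].
#'
#' @return A data.frame with columns `snp_id`, `or`, `ci_low`, `ci_high`,
#'   `maf`, `p_rank`, `bf`, `bf_rank`, `delta_r2`, `rank_r2`, `delta_r5`,
#'   `rank_r5`, `group`.
#' @export
casp8_top_snps <- function() {
  utils::read.table(system.file("extdata", "icogs_casp8_top20.tsv",
                                package = "ebfine"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Published group prior probabilities from the iCOGS CASP8 analysis
#'
#' The elicited per-group prior probabilities of causal association used in
#' the iCOGS CASP8 analysis, for common ratios R = 5 and R = 2 (p0 = 0.4,
#' four functional groups).
#'
#' @return A data.frame with columns `R`, `group`, `delta`.
#' @export
casp8_group_priors <- function() {
  utils::read.table(system.file("extdata", "icogs_casp8_group_priors.tsv",
                                package = "ebfine"),
                    header = TRUE, sep = "\t")
}
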