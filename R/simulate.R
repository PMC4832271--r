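#' Simulate a retrospective case-control genotype dataset
#'
#' Individuals are formed by drawing two haplotypes uniformly (with
#' replacement) from a reference panel; disease status follows a logistic
#' (multiplicative odds) model with per-allele log odds ratio
#' `log(or_per_allele)` at the single causal site, with the intercept solved
#' so the population prevalence matches `prevalence`. Cases and controls are
#' accumulated by rejection sampling until both quotas are met exactly,
#' mimicking retrospective ascertainment.
#'
#' @param panel A `haplotype_panel` from [make_haplotype_panel()].
#' @param causal_index Column index of the causal site in the panel.
#' @param or_per_allele Per-allele odds ratio (> 0) at the causal site.
#' @param n_cases,n_controls Exact numbers of cases and controls to sample.
#' @param prevalence Population disease prevalence in (0, 1). Bayes factors
#'   downstream depend only on the estimated log odds ratio and its variance,
#'   so this mainly controls sampling cost; default 0.01.
#' @param seed Integer seed; the dataset is a deterministic function of seed
#'   and parameters.
#' @param max_draws Retry cap on the total number of individuals simulated
#'   before giving up on an unreachable quota.
#' @return An object of class `case_control_dataset`: list with `dosages`
#'   (N x M integer matrix of minor-allele counts, cases first), `phenotype`
#'   (1 = case), `snp_ids`, `positions`, `causal_index`, `seed`.
#' @export
simulate_case_control <- function(panel, causal_index, or_per_allele,
                                  n_cases, n_controls, prevalence = 0.01,
                                  seed = 1L, max_draws = 1e7) {
  stopifnot(inherits(panel, "haplotype_panel"))
  M <- ncol(panel$alleles)
  H <- nrow(panel$alleles)
  if (causal_index < 1L || causal_index > M)
    stopf("`causal_index` must be in 1..%d", M)
  check_scalar_number(or_per_allele, "or_per_allele", 0, Inf, open_lower = TRUE)
  check_scalar_number(prevalence, "prevalence", 0, 1,
                      open_lower = TRUE, open_upper = TRUE)
  f_c <- mean(panel$alleles[, causal_index])
  if (f_c <= 0 || f_c >= 1)
    stopf("causal site %d is monomorphic in the panel", causal_index)

  beta1 <- log(or_per_allele)
  # Intercept matching the requested prevalence under the causal-site
  # genotype distribution (independent haplotype draws imply HWE).
  pg <- stats::dbinom(0:2, 2L, f_c)
  beta0 <- stats::uniroot(
    function(b0) sum(pg * stats::plogis(b0 + beta1 * (0:2))) - prevalence,
    c(-50, 50), tol = 1e-12)$root

  with_seed(seed, {
    case_h1 <- integer(0); case_h2 <- integer(0)
    ctrl_h1 <- integer(0); ctrl_h2 <- integer(0)
    drawn <- 0
    batch <- max(20000L, min(2000000L,
                             ceiling((n_cases + n_controls) / prevalence / 10)))
    while (length(case_h1) < n_cases || length(ctrl_h1) < n_controls) {
      if (drawn >= max_draws)
        stopf(paste0("case/control quota not reached after %g simulated ",
                     "individuals (prevalence %g); increase `max_draws` or ",
                     "the prevalence"), drawn, prevalence,
              class = "ebfine_quota_error")
      h1 <- sample.int(H, batch, replace = TRUE)
      h2 <- sample.int(H, batch, replace = TRUE)
      g <- panel$alleles[cbind(h1, causal_index)] +
        panel$alleles[cbind(h2, causal_index)]
      y <- stats::rbinom(batch, 1L, stats::plogis(beta0 + beta1 * g))
      drawn <- drawn + batch
      need_ca <- n_cases - length(case_h1)
      need_co <- n_controls - length(ctrl_h1)
      ca <- which(y == 1L); co <- which(y == 0L)
      if (need_ca > 0L && length(ca)) {
        keep <- ca[seq_len(min(need_ca, length(ca)))]
        case_h1 <- c(case_h1, h1[keep]); case_h2 <- c(case_h2, h2[keep])
      }
      if (need_co > 0L && length(co)) {
        keep <- co[seq_len(min(need_co, length(co)))]
        ctrl_h1 <- c(ctrl_h1, h1[keep]); ctrl_h2 <- c(ctrl_h2, h2[keep])
      }
    }
    i1 <- c(case_h1, ctrl_h1); i2 <- c(case_h2, ctrl_h2)
    dos <- panel$alleles[i1, , drop = FALSE] + panel$alleles[i2, , drop = FALSE]
    dimnames(dos) <- NULL
    structure(list(
      dosages = dos,
      phenotype = rep(c(1L, 0L), c(n_cases, n_controls)),
      snp_ids = sprintf("snp_%04d", seq_len(M)),
      positions = panel$positions,
      causal_index = as.integer(causal_index),
      seed = seed), class = "case_control_dataset")
  })
}

#' @export
print.case_control_dataset <- function(x, ...) {
  cat(sprintf("<case_control_dataset> %d cases + %d controls x %d SNPs; causal index %s\n",
              sum(x$phenotype == 1L), sum(x$phenotype == 0L),
              ncol(x$dosages),
              if (is.na(x$causal_index %||% NA)) "unknown" else x$causal_index))
  invisible(x)
}

#' Assign SNPs to functional prior-probability groups by proportion
#'
#' Partitions `n_snps` SNPs into `J` groups either with exact counts
#' (largest-remainder rounding of `n_snps * group_fractions`, then a random
#' permutation of the labels) or by independent multinomial draws.
#'
#' @param n_snps Number of SNPs.
#' @param group_fractions Length-`J` vector of proportions summing to 1
#'   (ordered from the "very unlikely causal" group 1 upwards).
#' @param seed Integer seed controlling the label permutation / draws.
#' @param exact If `TRUE` (default), group sizes equal the largest-remainder
#'   rounding of the expected counts exactly.
#' @return A `group_assignment`: list with `group` (per-SNP integer in
#'   `1..J`) and `sizes`.
#' @export
annotate_snps <- function(n_snps, group_fractions, seed = 1L, exact = TRUE) {
  J <- length(group_fractions)
  if (J < 1L) stopf("at least one group is required")
  if (any(group_fractions < 0)) stopf("group fractions must be >= 0")
  tot <- sum(group_fractions)
  if (abs(tot - 1) > 1e-8) stopf("group fractions must sum to 1 (got %g)", tot)

  with_seed(seed, {
    if (exact) {
      q <- n_snps * group_fractions
      counts <- floor(q)
      short <- n_snps - sum(counts)
      if (short > 0L) {
        add <- order(q - counts, decreasing = TRUE)[seq_len(short)]
        counts[add] <- counts[add] + 1L
      }
      group <- sample(rep.int(seq_len(J), counts))
    } else {
      group <- sample.int(J, n_snps, replace = TRUE, prob = group_fractions)
    }
    structure(list(group = as.integer(group),
                   sizes = tabulate(group, nbins = J)),
              class = "group_assignment")
  })
}

#' @export
print.group_assignment <- function(x, ...) {
  cat("<group_assignment> sizes:", paste(x$sizes, collapse = "/"), "\n")
  invisible(x)
}

#' Generate a synthetic functional-annotation table for given groups
#'
#' For each SNP, draws a combination of the four binary summary variables
#' (regional location, histone modification, chromatin availability,
#' conservation) that maps to the SNP's group under the default decision tree
#' ([default_group_rules()]), then masks a share of the zero values as `NA`
#' to emulate below-threshold missingness in public annotation tracks.
#' Running [assign_groups()] on the result recovers the input groups exactly,
#' which makes the table a self-consistent stand-in for a real annotation
#' download.
#'
#' @param groups Integer vector of group labels in 1..4, or a
#'   `group_assignment`.
#' @param missing_rate Probability that a zero entry is recorded as `NA`.
#' @param seed Integer seed.
#' @return A data.frame with columns `snp_id`, `regional_location`,
#'   `histone_modification`, `availability`, `conservation`.
#' @export
simulate_annotations <- function(groups, missing_rate = 0.3, seed = 1L) {
  if (inherits(groups, "group_assignment")) groups <- groups$group
  if (any(!groups %in% 1:4))
    stopf("synthetic annotations are defined for the default 4-group tree")
  check_scalar_number(missing_rate, "missing_rate", 0, 1)

  combos <- expand.grid(regional_location = 0:1, histone_modification = 0:1,
                        availability = 0:1, conservation = 0:1)
  combos$snp_id <- sprintf("c%02d", seq_len(nrow(combos)))
  combo_group <- assign_groups(combos)$group

  with_seed(seed, {
    pick <- vapply(groups, function(g) {
      cand <- which(combo_group == g)
      cand[sample.int(length(cand), 1L)]
    }, integer(1))
    ann <- combos[pick, c("regional_location", "histone_modification",
                          "availability", "conservation")]
    rownames(ann) <- NULL
    for (v in names(ann)) {
      mask <- ann[[v]] == 0L & stats::runif(nrow(ann)) < missing_rate
      ann[[v]][mask] <- NA_integer_
    }
    cbind(data.frame(snp_id = sprintf("snp_%04d", seq_along(groups)),
                     stringsAsFactors = FALSE), ann)
  })
}
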