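#' Run a full simulate / summarize / rank / evaluate scenario
#'
#' Orchestrates one simulation-study scenario end to end: build an LD-block
#' haplotype panel, assign SNPs to functional groups, pick a causal SNP from
#' the requested group, simulate replicate case-control datasets, fit the
#' per-SNP logistic models, estimate the empirical-Bayes prior variance per
#' replicate, compute Bayes factors and posterior probabilities, and reduce
#' both statistics to threshold-averaged ROC curves. All stochastic steps
#' derive from `config$seed`, so identical configurations give identical
#' outputs. Artifacts (scores, ROC curves, a JSON summary and a manifest)
#' are written under `config$out_dir` when given.
#'
#' @param config List of scenario parameters; missing entries fall back to
#'   defaults (`n_snps = 120`, `n_haplotypes = 1000`, `maf = 0.18`,
#'   `or_per_allele = 1.1`, `n_cases = 200`, `n_controls = 200`,
#'   `prevalence = 0.01`, `n_replicates = 20`, `p_percent = 30`,
#'   `group_fractions = c(1698, 780, 362, 31)/2871`, `p0 = 0.4`, `R = 5`,
#'   `causal_group = 4`, `n_thresholds = 512`, `seed = 1`,
#'   `out_dir = NULL`).
#' @return Invisibly, a list with the replicate score sets (`delta_reps`,
#'   `bf_reps`), the ROC curves and AUCs, the per-replicate prior variances
#'   `w_eb`, the group assignment and solved priors.
#' @export
run_scenario <- function(config = list()) {
  cfg <- utils::modifyList(list(
    n_snps = 120L, n_haplotypes = 1000L, maf = 0.18, or_per_allele = 1.1,
    n_cases = 200L, n_controls = 200L, prevalence = 0.01,
    n_replicates = 20L, p_percent = 30,
    group_fractions = c(1698, 780, 362, 31) / 2871, p0 = 0.4, R = 5,
    causal_group = 4L, n_thresholds = 512L, seed = 1L, out_dir = NULL),
    config)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("scenario stage `%s` failed: %s", name, conditionMessage(e)))
  }

  panel <- stage("panel", make_haplotype_panel(
    cfg$n_haplotypes, cfg$n_snps, seed = cfg$seed))
  groups <- stage("groups", annotate_snps(
    cfg$n_snps, cfg$group_fractions, seed = cfg$seed + 1L))
  priors <- stage("elicit", solve_delta_linear(
    elicitation_spec(groups$sizes, cfg$p0, cfg$R)))

  candidates <- which(groups$group == cfg$causal_group)
  if (!length(candidates))
    stopf(paste0("no SNP fell into causal_group %d (group sizes %s); ",
                 "increase n_snps or choose another group"),
          cfg$causal_group, paste(groups$sizes, collapse = "/"))
  # prefer a causal SNP whose panel MAF is close to the requested value
  freq <- pmin(panel_freq(panel), 1 - panel_freq(panel))
  causal_index <- candidates[which.min(abs(freq[candidates] - cfg$maf))]

  delta_reps <- vector("list", cfg$n_replicates)
  bf_reps <- vector("list", cfg$n_replicates)
  w_eb <- numeric(cfg$n_replicates)
  stage("replicates", for (r in seq_len(cfg$n_replicates)) {
    ds <- simulate_case_control(panel, causal_index, cfg$or_per_allele,
                                cfg$n_cases, cfg$n_controls, cfg$prevalence,
                                seed = cfg$seed + 100L + r)
    summ <- summarize_all(ds)
    ok <- summ$flag == "ok"
    w <- surrogate_w_eb(summ, cfg$p_percent)
    w_eb[r] <- w$W
    tbl <- posterior_table(summ, groups$group, priors, w)
    causal <- seq_len(cfg$n_snps) == causal_index
    delta_reps[[r]] <- list(scores = stats::qlogis(tbl$Delta[ok]),
                            causal = causal[ok])
    bf_reps[[r]] <- list(scores = tbl$log_bf[ok], causal = causal[ok])
  })

  roc_delta <- stage("roc", roc_threshold_average(delta_reps, cfg$n_thresholds))
  roc_bf <- stage("roc", roc_threshold_average(bf_reps, cfg$n_thresholds))

  res <- list(config = cfg, causal_index = causal_index, groups = groups,
              priors = priors, w_eb = w_eb,
              delta_reps = delta_reps, bf_reps = bf_reps,
              roc_delta = roc_delta, roc_bf = roc_bf,
              auc_delta = auc(roc_delta), auc_bf = auc(roc_bf))

  if (!is.null(cfg$out_dir)) stage("write", write_scenario(res, cfg$out_dir))
  invisible(res)
}

write_scenario <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- res$config
  write_curve <- function(curve, path) {
    utils::write.table(
      data.frame(threshold = curve$thresholds, mean_fpr = curve$mean_fpr,
                 mean_tpr = curve$mean_tpr),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_scores <- function(reps, path) {
    m <- t(vapply(reps, function(r) r$scores, numeric(length(reps[[1]]$scores))))
    df <- as.data.frame(m)
    names(df) <- sprintf("snp_%04d", which_cols <- seq_len(ncol(m)))
    df <- cbind(replicate = seq_len(nrow(m)), df)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_curve(res$roc_delta, file.path(out_dir, "roc_Delta.tsv"))
  write_curve(res$roc_bf, file.path(out_dir, "roc_bf.tsv"))
  write_scores(res$delta_reps, file.path(out_dir, "scores_Delta.tsv"))
  write_scores(res$bf_reps, file.path(out_dir, "scores_bf.tsv"))
  summary <- list(auc_delta = res$auc_delta, auc_bf = res$auc_bf,
                  causal_index = res$causal_index,
                  w_eb_quartiles = unname(stats::quantile(res$w_eb)),
                  delta = res$priors$delta,
                  group_sizes = res$groups$sizes)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(package = "ebfine",
                   version = as.character(utils::packageVersion("ebfine")),
                   r_version = R.version.string,
                   seed = cfg$seed,
                   config = cfg[setdiff(names(cfg), "out_dir")])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
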