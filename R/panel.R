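#' Adjacent-site correlation profile for an LD-block panel
#'
#' Builds the vector of adjacent-site haplotype correlations used by
#' [make_haplotype_panel()]: a constant correlation `r_within` between
#' neighbouring sites inside each block and zero across block boundaries.
#' This first-order Markov block structure is a controllable stand-in for the
#' LD mosaic of a real fine-mapping region.
#'
#' @param n_snps Number of sites in the panel.
#' @param block_sizes Integer vector of block lengths; recycled/truncated to
#'   cover `n_snps` sites.
#' @param r_within Correlation between adjacent sites within a block, in
#'   `[0, 1]`.
#' @return Numeric vector of length `n_snps - 1` with the correlation between
#'   each pair of adjacent sites.
#' @export
ld_blocks <- function(n_snps, block_sizes, r_within = 0.9) {
  if (n_snps < 2L) return(numeric(0))
  check_scalar_number(r_within, "r_within", 0, 1)
  block_sizes <- as.integer(block_sizes)
  if (any(block_sizes < 1L)) stopf("block sizes must be >= 1")
  sizes <- rep(block_sizes, length.out = n_snps)
  sizes <- sizes[cumsum(sizes) - sizes < n_snps]
  block_of <- rep(seq_along(sizes), sizes)[seq_len(n_snps)]
  ifelse(block_of[-n_snps] == block_of[-1L], r_within, 0)
}

default_maf_sampler <- function(n) {
  # Skewed spectrum with median MAF near 0.17, typical of a dense
  # fine-mapping panel after rare-variant exclusion.
  0.01 + 0.49 * stats::rbeta(n, 1.2, 2.2)
}

#' Simulate a haplotype reference panel with block LD
#'
#' Generates `n_haplotypes` binary haplotypes over `n_snps` sites using a
#' first-order Markov chain along the chromosome: each site's allele is
#' correlated with the previous site's allele according to an adjacent-site
#' correlation profile (see [ld_blocks()]), giving a block-wise r-squared
#' decay. The panel plays the role of a population reference panel (e.g.
#' phased haplotypes for a 1 Mb fine-mapping region) from which case-control
#' genotypes are later resampled.
#'
#' @param n_haplotypes Even number of haplotypes, at least 4.
#' @param n_snps Number of polymorphic sites.
#' @param maf_sampler Either a function `f(n)` returning `n` target minor
#'   allele frequencies in `(0, 0.5]`, or a numeric vector of length `n_snps`
#'   of target MAFs. Default: a Beta(1.2, 2.2) spectrum scaled to
#'   `(0.01, 0.5)`.
#' @param ld_profile Either a numeric vector of length `n_snps - 1` of
#'   adjacent-site correlations in `[0, 1]`, a single number applied to all
#'   adjacent pairs, or a list `list(block_sizes=, r_within=)` passed to
#'   [ld_blocks()]. Default: blocks of 10-40 sites with `r_within = 0.9`.
#' @param seed Integer seed; the panel is a deterministic function of the
#'   seed and parameters.
#' @param positions Optional strictly increasing 1-based base-pair positions;
#'   by default drawn without replacement from a 1 Mb window.
#' @return An object of class `haplotype_panel`: a list with `alleles`
#'   (haplotypes x sites 0/1 matrix), `positions`, `target_mafs` and the
#'   adjacent correlation profile `adj_r`.
#' @export
make_haplotype_panel <- function(n_haplotypes, n_snps, maf_sampler = NULL,
                                 ld_profile = NULL, seed = 1L,
                                 positions = NULL) {
  if (n_haplotypes < 4L || n_haplotypes %% 2L != 0L)
    stopf("`n_haplotypes` must be an even number >= 4")
  if (n_snps < 1L) stopf("`n_snps` must be >= 1")

  with_seed(seed, {
    mafs <- if (is.function(maf_sampler)) {
      maf_sampler(n_snps)
    } else if (is.numeric(maf_sampler)) {
      if (length(maf_sampler) == 1L) rep(maf_sampler, n_snps) else maf_sampler
    } else {
      default_maf_sampler(n_snps)
    }
    if (length(mafs) != n_snps)
      stopf("maf_sampler produced %d frequencies for %d sites",
            length(mafs), n_snps)
    if (any(mafs <= 0 | mafs > 0.5))
      stopf("target MAFs must lie in (0, 0.5]; a MAF of 0 would make the site monomorphic")

    adj_r <- if (is.null(ld_profile)) {
      ld_blocks(n_snps, sample(10:40, max(1L, ceiling(n_snps / 10)),
                               replace = TRUE), 0.9)
    } else if (is.list(ld_profile)) {
      ld_blocks(n_snps, ld_profile$block_sizes,
                ld_profile$r_within %||% 0.9)
    } else if (length(ld_profile) == 1L) {
      rep(as.numeric(ld_profile), max(0L, n_snps - 1L))
    } else {
      as.numeric(ld_profile)
    }
    if (length(adj_r) != max(0L, n_snps - 1L))
      stopf("ld_profile has %d correlations for %d adjacent pairs",
            length(adj_r), n_snps - 1L)
    if (any(adj_r < 0 | adj_r > 1))
      stopf("adjacent-site correlations must lie in [0, 1]")

    H <- as.integer(n_haplotypes)
    al <- matrix(0L, nrow = H, ncol = n_snps)
    al[, 1L] <- draw_polymorphic(H, rep(mafs[1L], H))
    for (m in seq_len(n_snps)[-1L]) {
      f_prev <- mafs[m - 1L]; f <- mafs[m]; r <- adj_r[m - 1L]
      # Conditional Bernoulli giving corr(X_{m-1}, X_m) = r for the target
      # frequencies; probabilities clamped to [0,1] when the pair (f_prev, f)
      # cannot support the requested correlation.
      slope <- r * sqrt(f * (1 - f) / (f_prev * (1 - f_prev)))
      p <- pmin(1, pmax(0, f + slope * (al[, m - 1L] - f_prev)))
      al[, m] <- draw_polymorphic(H, p)
    }

    pos <- positions %||% (sort(sample.int(999999L, n_snps)) + 201566128L)
    if (any(diff(pos) <= 0)) stopf("positions must be strictly increasing")

    structure(list(alleles = al, positions = as.integer(pos),
                   target_mafs = mafs, adj_r = adj_r, seed = seed),
              class = "haplotype_panel")
  })
}

# Draw one column of Bernoulli(p) alleles, redrawing (then flipping one entry
# as a last resort) if the realized column is monomorphic, so that every
# panel site has haplotype frequency strictly inside (0, 1).
draw_polymorphic <- function(H, p) {
  for (i in 1:20) {
    x <- stats::rbinom(H, 1L, p)
    s <- sum(x)
    if (s > 0L && s < H) return(x)
  }
  x[sample.int(H, 1L)] <- 1L - x[1L]
  x
}

#' Realized per-site allele frequency of a haplotype panel
#' @param panel A `haplotype_panel`.
#' @return Numeric vector of allele-1 frequencies.
#' @export
panel_freq <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  colMeans(panel$alleles)
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %d haplotypes x %d sites, %d LD-independent adjacencies\n",
              nrow(x$alleles), ncol(x$alleles), sum(x$adj_r == 0)))
  invisible(x)
}
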