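# Readers and writers for the Oxford GEN/SAMPLE dialect and plain TSV
# exchange formats.

#' Write a case-control dataset as Oxford GEN + SAMPLE files
#'
#' GEN lines carry 5 leading columns (chromosome, SNP id, position, alleleA,
#' alleleB) followed by three genotype probabilities per subject; alleleB is
#' the dosage (minor) allele. Integer dosages are written as hard calls;
#' fractional dosages are split between the two flanking genotype classes so
#' the expected dosage round-trips exactly.
#'
#' @param dataset A `case_control_dataset`.
#' @param gen_file,sample_file Output paths.
#' @param chr Chromosome label for column 1.
#' @return Invisibly, the two paths.
#' @export
write_gen_sample <- function(dataset, gen_file, sample_file, chr = "02") {
  dos <- dataset$dosages
  N <- nrow(dos); M <- ncol(dos)
  lines <- character(M)
  for (j in seq_len(M)) {
    d <- dos[, j]
    lo <- pmin(floor(d), 1)           # lower flanking genotype (0 or 1)
    frac <- d - lo
    probs <- matrix(0, nrow = 3, ncol = N)
    probs[cbind(lo + 1, seq_len(N))] <- 1 - frac
    probs[cbind(lo + 2, seq_len(N))] <- probs[cbind(lo + 2, seq_len(N))] + frac
    lines[j] <- paste(chr, dataset$snp_ids[j], dataset$positions[j], "A", "B",
                      paste(formatC(probs, format = "g", digits = 10),
                            collapse = " "))
  }
  writeLines(lines, gen_file)
  writeLines(c("ID_1 ID_2 missing pheno", "0 0 0 B",
               sprintf("id%06d id%06d 0 %d", seq_len(N), seq_len(N),
                       dataset$phenotype)), sample_file)
  invisible(c(gen = gen_file, sample = sample_file))
}

#' Read Oxford GEN + SAMPLE files into a case-control dataset
#'
#' Expected dosage is computed as `P(het) + 2 P(hom-alleleB)`. Genotype
#' probability triples whose sum differs from 1 by more than `tol` trigger a
#' warning and are renormalized; structurally malformed lines (wrong field
#' count, non-numeric probabilities) raise an error naming the line.
#'
#' @param gen_file,sample_file Input paths.
#' @param tol Tolerance on each probability-triple sum (default 1e-3).
#' @return A `case_control_dataset` (with unknown `causal_index`).
#' @export
read_gen_sample <- function(gen_file, sample_file, tol = 1e-3) {
  samp <- utils::read.table(sample_file, header = TRUE,
                            stringsAsFactors = FALSE)
  samp <- samp[-1L, , drop = FALSE]       # drop the type-code line
  phenotype <- as.integer(samp$pheno)
  if (any(!phenotype %in% c(0L, 1L)))
    stopf("SAMPLE `pheno` column must be binary 0/1")
  N <- length(phenotype)

  lines <- readLines(gen_file)
  M <- length(lines)
  dos <- matrix(NA_real_, nrow = N, ncol = M)
  ids <- character(M); pos <- integer(M)
  renorm <- 0L
  for (j in seq_len(M)) {
    f <- strsplit(trimws(lines[j]), "[ \t]+")[[1L]]
    if (length(f) != 5L + 3L * N)
      stopf("GEN line %d: expected %d fields, found %d", j, 5L + 3L * N,
            length(f))
    ids[j] <- f[2L]
    pos[j] <- as.integer(f[3L])
    p <- suppressWarnings(as.numeric(f[-(1:5)]))
    if (anyNA(p)) stopf("GEN line %d: non-numeric genotype probability", j)
    p <- matrix(p, nrow = 3L)
    sums <- colSums(p)
    bad <- abs(sums - 1) > tol
    if (any(bad)) {
      renorm <- renorm + sum(bad)
      p <- sweep(p, 2L, sums, "/")
    }
    dos[, j] <- p[2L, ] + 2 * p[3L, ]
  }
  if (renorm > 0L)
    warning(sprintf("%d genotype probability triples did not sum to 1 (tol %g) and were renormalized",
                    renorm, tol), call. = FALSE)
  structure(list(dosages = dos, phenotype = phenotype, snp_ids = ids,
                 positions = pos, causal_index = NA_integer_, seed = NA),
            class = "case_control_dataset")
}

#' Write / read a dosage matrix as TSV
#'
#' Wide layout: one row per subject, first column `phenotype`, remaining
#' columns one per SNP (named by SNP id).
#'
#' @param dataset A `case_control_dataset`.
#' @param file Path.
#' @return `write_dosage_tsv` invisibly returns `file`; `read_dosage_tsv`
#'   returns a `case_control_dataset`.
#' @export
write_dosage_tsv <- function(dataset, file) {
  df <- as.data.frame(dataset$dosages)
  names(df) <- dataset$snp_ids
  df <- cbind(phenotype = dataset$phenotype, df)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t", check.names = FALSE)
  structure(list(dosages = as.matrix(df[-1L]),
                 phenotype = as.integer(df$phenotype),
                 snp_ids = names(df)[-1L],
                 positions = rep(NA_integer_, ncol(df) - 1L),
                 causal_index = NA_integer_, seed = NA),
            class = "case_control_dataset")
}

#' Write / read per-SNP association summaries as TSV
#'
#' @param summaries Data frame from [summarize_all()].
#' @param file Path.
#' @export
write_snp_summaries <- function(summaries, file) {
  utils::write.table(summaries, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_snp_summaries
#' @export
read_snp_summaries <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write a per-SNP group assignment as TSV
#'
#' @param groups A `group_assignment` (with `snp_id` when available).
#' @param file Path.
#' @export
write_groups_tsv <- function(groups, file) {
  ids <- groups$snp_id %||% sprintf("snp_%04d", seq_along(groups$group))
  utils::write.table(data.frame(snp_id = ids, group = groups$group),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_groups_tsv
#' @export
read_groups_tsv <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  structure(list(group = as.integer(df$group),
                 sizes = tabulate(df$group), snp_id = df$snp_id),
            class = "group_assignment")
}
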