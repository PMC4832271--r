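#' Default decision tree mapping functional summary variables to groups
#'
#' Ordered rule table used by [assign_groups()]. Each row gives values of the
#' four binary summary variables (regional location in a disease gene,
#' histone-modification signal, chromatin availability, evolutionary
#' conservation); `NA` entries are wildcards. The first matching row assigns
#' the group. The shipped tree puts SNPs inside a disease gene that carry a
#' histone-modification mark plus open chromatin or conservation evidence
#' into the "very likely causal" group 4, and SNPs with neither location nor
#' histone evidence into the "very unlikely" group 1.
#'
#' @return A data.frame of ordered rules with a terminal `group` column.
#' @export
default_group_rules <- function() {
  data.frame(
    regional_location    = c(1L, 1L, 1L, 1L, 1L, 0L, 0L, 0L),
    histone_modification = c(1L, 1L, 1L, 0L, 0L, 1L, 1L, 0L),
    availability         = c(1L, NA, 0L, 0L, NA, 0L, NA, NA),
    conservation         = c(NA, 1L, 0L, 0L, NA, 0L, NA, NA),
    group                = c(4L, 4L, 3L, 2L, 3L, 2L, 3L, 1L))
}

#' Partition SNPs into prior-probability groups via decision rules
#'
#' Applies an ordered rule table to per-SNP binary functional summary
#' variables, yielding a group label in `1..J` for each SNP. Missing values
#' are replaced by 0 first, on the assumption that an absent annotation means
#' the underlying measurement did not exceed its reporting threshold.
#'
#' @param annotations Data frame with one row per SNP containing the
#'   variables named in `rules` (0/1 or `NA`), and optionally `snp_id`.
#' @param rules Ordered rule data.frame as in [default_group_rules()]: one
#'   column per summary variable (`NA` = wildcard) plus a `group` column.
#' @return A `group_assignment` (fields `group`, `sizes`, and `snp_id` when
#'   present in the input).
#' @export
assign_groups <- function(annotations, rules = default_group_rules()) {
  vars <- setdiff(names(rules), "group")
  missing_vars <- setdiff(vars, names(annotations))
  if (length(missing_vars))
    stopf("annotation table lacks summary variable(s): %s",
          paste(missing_vars, collapse = ", "))
  A <- annotations[vars]
  for (v in vars) {
    A[[v]][is.na(A[[v]])] <- 0L
    if (!all(A[[v]] %in% c(0L, 1L)))
      stopf("summary variable `%s` must be binary 0/1 after missing-value handling", v)
  }
  group <- rep(NA_integer_, nrow(A))
  for (r in seq_len(nrow(rules))) {
    match_r <- is.na(group)
    for (v in vars) {
      rv <- rules[[v]][r]
      if (!is.na(rv)) match_r <- match_r & (A[[v]] == rv)
    }
    group[match_r] <- rules$group[r]
  }
  if (anyNA(group)) {
    i <- which(is.na(group))[1L]
    stopf("no rule matches the summary-variable combination (%s) of record %d",
          paste(sprintf("%s=%d", vars, unlist(A[i, ])), collapse = ", "), i)
  }
  out <- list(group = group, sizes = tabulate(group, nbins = max(rules$group)))
  if (!is.null(annotations$snp_id)) out$snp_id <- annotations$snp_id
  structure(out, class = "group_assignment")
}

#' Elicitation specification for group prior probabilities
#'
#' Bundles the quantities elicited from a domain expert: the group sizes
#' `n`, the prior probability `p0` that no SNP in the region is causal, and
#' the multiplicative increase `R` in the per-SNP prior probability between
#' adjacent groups (a scalar common ratio, or `J - 1` group-specific
#' ratios). Optionally, prior probabilities `(p0, p1, p2)` on the number of
#' causal SNPs for the causal-count solver.
#'
#' @param n Integer vector of group sizes, ordered from group 1 upwards.
#' @param p0 Prior probability that there is no causal SNP, in (0, 1).
#' @param R Common ratio (> 0) or length `J - 1` vector of ratios.
#' @param causal_count_probs Optional numeric vector `(p0, p1, p2)` summing
#'   to 1.
#' @return An object of class `elicitation_spec`.
#' @export
elicitation_spec <- function(n, p0, R, causal_count_probs = NULL) {
  if (any(n < 0) || sum(n) < 1) stopf("group sizes must be >= 0 and sum to >= 1")
  check_scalar_number(p0, "p0", 0, 1, open_lower = TRUE, open_upper = TRUE)
  J <- length(n)
  if (!length(R) %in% c(1L, max(1L, J - 1L)))
    stopf("`R` must be a scalar or have length J - 1 = %d", J - 1L)
  if (any(R <= 0)) stopf("ratios `R` must be > 0")
  if (!is.null(causal_count_probs)) {
    # taken as given non-negative weights (p0, p1, p2); the identity they
    # enter is solved literally, so no sum-to-one constraint is imposed
    if (length(causal_count_probs) != 3L || any(causal_count_probs < 0))
      stopf("`causal_count_probs` must be three non-negative weights (p0, p1, p2)")
  }
  structure(list(n = as.numeric(n), p0 = p0, R = as.numeric(R), J = J,
                 causal_count_probs = causal_count_probs),
            class = "elicitation_spec")
}

as_spec <- function(spec, p0 = NULL, R = NULL, causal_count_probs = NULL) {
  if (inherits(spec, "elicitation_spec")) return(spec)
  elicitation_spec(spec, p0, R, causal_count_probs)
}

# Cumulative group multipliers rho_j = prod_{k<j} R_k (rho_1 = 1).
group_ratios <- function(spec) {
  R <- if (length(spec$R) == 1L) rep(spec$R, max(0L, spec$J - 1L)) else spec$R
  cumprod(c(1, R))
}

new_group_priors <- function(delta, method, spec) {
  if (any(delta <= 0 | delta >= 1))
    stopf("solved delta values fall outside (0, 1): check p0, R and group sizes",
          class = "ebfine_invalid_delta")
  structure(list(delta = delta, method = method,
                 achieved_p0 = prod((1 - delta)^spec$n),
                 p0 = spec$p0, n = spec$n, rho = group_ratios(spec)),
            class = "group_priors")
}

#' @export
print.group_priors <- function(x, ...) {
  cat(sprintf("<group_priors> method %s: delta = %s; achieved p0 = %.6g (target %.6g)\n",
              x$method, paste(signif(x$delta, 4), collapse = ", "),
              x$achieved_p0, x$p0))
  invisible(x)
}

#' First-order (linear) elicitation solver for group priors
#'
#' Solves the linearized constraint \eqn{1 - p_0 = \sum_j n_j \delta_{[j]}}
#' under \eqn{\delta_{[j+1]} = R\,\delta_{[j]}}, giving
#' \deqn{\delta_{[1]} = (1 - p_0) / (n_J R^{J-1} + \dots + n_2 R + n_1)}
#' and the remaining values by successive multiplication by `R`. Accurate
#' when every \eqn{n_j \delta_{[j]}} is small; see
#' [approximation_diagnostics()] for when it is not.
#'
#' @param spec An [elicitation_spec()], or the group-size vector `n` (with
#'   `p0` and `R` supplied).
#' @param p0,R See [elicitation_spec()]; `R` must be a common (scalar) ratio
#'   for this solver.
#' @return A `group_priors` object with the solved `delta` vector and the
#'   recomputed `achieved_p0` \eqn{= \prod_j (1 - \delta_{[j]})^{n_j}}.
#' @export
solve_delta_linear <- function(spec, p0 = NULL, R = NULL) {
  spec <- as_spec(spec, p0, R)
  if (length(spec$R) != 1L && spec$J > 1L)
    stopf("the linear solver requires a common ratio R")
  rho <- group_ratios(spec)
  denom <- sum(spec$n * rho)
  if (denom <= 0) stopf("all group sizes are zero")
  d1 <- (1 - spec$p0) / denom
  new_group_priors(d1 * rho, "linear", spec)
}

#' Second-order (quadratic) elicitation solver for group priors
#'
#' Retains quadratic terms of the expanded constraint, solving
#' \eqn{a \delta_{[1]}^2 + b \delta_{[1]} + c = 0} with
#' \eqn{a = \sum_j n_j^2 R^{2j-2} + \sum_{j < j^*} n_j n_{j^*} R^{j+j^*-2}},
#' \eqn{b = -\sum_j n_j R^{j-1}} and \eqn{c = 1 - p_0}; the smaller positive
#' root is returned. When the discriminant is negative the solver signals a
#' condition of class `ebfine_no_real_root`, and the exact root finder
#' [solve_delta_exact()] should be used instead.
#'
#' @inheritParams solve_delta_linear
#' @return A `group_priors` object.
#' @export
solve_delta_quadratic <- function(spec, p0 = NULL, R = NULL) {
  spec <- as_spec(spec, p0, R)
  if (length(spec$R) != 1L && spec$J > 1L)
    stopf("the quadratic solver requires a common ratio R")
  rho <- group_ratios(spec)
  aj <- spec$n * rho
  a <- sum(aj^2) + (sum(aj)^2 - sum(aj^2)) / 2
  b <- -sum(aj)
  c0 <- 1 - spec$p0
  disc <- b^2 - 4 * a * c0
  if (disc < 0)
    stopf(paste0("the quadratic elicitation equation has no real roots ",
                 "(discriminant %.4g); use solve_delta_exact()"), disc,
          class = "ebfine_no_real_root")
  d1 <- (-b - sqrt(disc)) / (2 * a)
  if (d1 <= 0)
    stopf("the quadratic elicitation equation has no positive root",
          class = "ebfine_no_real_root")
  new_group_priors(d1 * rho, "quadratic", spec)
}

#' Exact elicitation solver via bracketed root finding
#'
#' Solves the untruncated constraint
#' \eqn{p_0 = \prod_j (1 - \delta_{[j]})^{n_j}} for \eqn{\delta_{[1]}}
#' (with \eqn{\delta_{[j+1]} = R_j \delta_{[j]}}) by bracketed scalar root
#' finding on the log scale, followed by Newton polishing so the recomputed
#' product matches `p0` to within 1e-12. Group-specific ratios are allowed.
#'
#' @inheritParams solve_delta_linear
#' @return A `group_priors` object with `achieved_p0` equal to `p0` to
#'   1e-12.
#' @export
solve_delta_exact <- function(spec, p0 = NULL, R = NULL) {
  spec <- as_spec(spec, p0, R)
  rho <- group_ratios(spec)
  g <- function(d1) sum(spec$n * log1p(-d1 * rho)) - log(spec$p0)
  gprime <- function(d1) -sum(spec$n * rho / (1 - d1 * rho))
  upper <- (1 - 1e-9) / max(rho)
  if (g(upper) > 0)
    stopf("root bracket failure: even delta_J ~ 1 leaves the product above p0 = %g",
          spec$p0)
  d1 <- stats::uniroot(g, c(0, upper), tol = 1e-14)$root
  for (i in 1:8) {          # Newton polish to the 1e-12 product tolerance
    step <- g(d1) / gprime(d1)
    if (!is.finite(step)) break
    d1 <- d1 - step
    if (abs(step) < 1e-16 * max(d1, 1e-300)) break
  }
  new_group_priors(d1 * rho, "exact_root", spec)
}

#' Elicitation solver with a prior on the number of causal SNPs
#'
#' Replaces the independence assumption across SNPs with an explicit prior
#' `(p0, p1, p2)` on there being 0, 1 or 2 causal SNPs in the region,
#' yielding the quadratic identity
#' \deqn{1 = p_0 + p_1 A \delta_{[1]} + p_2 B \delta_{[1]}^2,}
#' where, with cumulative multipliers \eqn{\rho_j = \prod_{k<j} R_k},
#' \eqn{A = \sum_j n_j \rho_j} and
#' \eqn{B = \sum_j n_j^2 \rho_j^2 + \sum_{j<k} n_j n_k \rho_j \rho_k}.
#' The positive root for \eqn{\delta_{[1]}} is returned; group-specific
#' ratios are allowed. With `p1 = 1, p2 = 0` this reduces exactly to the
#' linear solver.
#'
#' @param spec An [elicitation_spec()] carrying `causal_count_probs`, or a
#'   group-size vector `n`.
#' @param causal_count_probs Non-negative weights `(p0, p1, p2)` on there
#'   being 0, 1 or 2 causal SNPs (used when `spec` is a plain size vector);
#'   solved literally, so the weights need not sum to 1.
#' @param R Common ratio or `J - 1` group-specific ratios.
#' @return A `group_priors` object with method `"causal_count"`.
#' @export
solve_delta_causal_count <- function(spec, causal_count_probs = NULL, R = NULL) {
  if (!inherits(spec, "elicitation_spec")) {
    if (is.null(causal_count_probs))
      stopf("`causal_count_probs` (p0, p1, p2) is required")
    spec <- elicitation_spec(spec, p0 = causal_count_probs[1L], R = R,
                             causal_count_probs = causal_count_probs)
  }
  pm <- spec$causal_count_probs
  if (is.null(pm)) stopf("`spec` carries no causal_count_probs")
  rho <- group_ratios(spec)
  aj <- spec$n * rho
  A <- sum(aj)
  B <- sum(aj^2) + (sum(aj)^2 - sum(aj^2)) / 2
  # p2*B*d^2 + p1*A*d - (1 - p0) = 0
  if (pm[3L] == 0 || B == 0) {
    if (pm[2L] * A <= 0)
      stopf("no positive root: p1 and the group sizes give a degenerate equation",
            class = "ebfine_no_real_root")
    d1 <- (1 - pm[1L]) / (pm[2L] * A)
  } else {
    disc <- (pm[2L] * A)^2 + 4 * pm[3L] * B * (1 - pm[1L])
    if (disc < 0)
      stopf("the causal-count quadratic has no real roots",
            class = "ebfine_no_real_root")
    d1 <- (-pm[2L] * A + sqrt(disc)) / (2 * pm[3L] * B)
    if (d1 <= 0)
      stopf("the causal-count quadratic has no positive root",
            class = "ebfine_no_real_root")
  }
  spec$p0 <- pm[1L]
  new_group_priors(d1 * rho, "causal_count", spec)
}

#' Diagnostics for the elicitation approximation
#'
#' Reports how well a solved set of group priors satisfies the untruncated
#' constraint, and where the truncated expansions are likely to break down:
#' the recomputed `achieved_p0` versus the target, the per-group mass
#' \eqn{n_j \delta_{[j]}}, the indicator \eqn{R^{j-1} / n_j} (the group with
#' the largest value is where extra expansion terms are needed first), and
#' the ratio of successive binomial-expansion terms
#' \eqn{\delta_{[j]} (n_j - 1) / 2}.
#'
#' @param priors A `group_priors` object from one of the solvers.
#' @return A list of class `elicitation_diagnostics`.
#' @export
approximation_diagnostics <- function(priors) {
  stopifnot(inherits(priors, "group_priors"))
  n <- priors$n; delta <- priors$delta; rho <- priors$rho
  indicator <- ifelse(n > 0, rho / n, Inf)
  structure(list(
    method = priors$method,
    target_p0 = priors$p0,
    achieved_p0 = priors$achieved_p0,
    abs_error = abs(priors$achieved_p0 - priors$p0),
    n_delta = n * delta,
    expansion_indicator = indicator,
    worst_group = which.max(indicator),
    term_ratio = delta * pmax(n - 1, 0) / 2), class = "elicitation_diagnostics")
}

#' @export
print.elicitation_diagnostics <- function(x, ...) {
  cat(sprintf("<elicitation_diagnostics> %s solver: achieved p0 %.6g vs target %.6g (|error| %.3g)\n",
              x$method, x$achieved_p0, x$target_p0, x$abs_error))
  cat("  n_j * delta_j:", paste(signif(x$n_delta, 3), collapse = ", "), "\n")
  cat(sprintf("  expansion indicator R^(j-1)/n_j worst in group %d\n",
              x$worst_group))
  invisible(x)
}
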