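# Group partition rules and the four elicitation solvers.

casp8_n <- c(1698, 780, 362, 31)

test_that("linear solver reproduces the published CASP8 group priors", {
  pr5 <- solve_delta_linear(casp8_n, 0.4, 5)
  expect_equal(pr5$delta[1], 0.6 / (31 * 125 + 362 * 25 + 780 * 5 + 1698))
  expect_equal(signif(pr5$delta[1], 2), 3.2e-5)
  expect_equal(signif(pr5$delta, 2), c(3.2e-5, 1.6e-4, 8.1e-4, 4.0e-3))
  pr2 <- solve_delta_linear(casp8_n, 0.4, 2)
  expect_equal(signif(pr2$delta[1], 2), 1.2e-4)
  expect_equal(solve_delta_linear(c(100), 0.9, 5)$delta, 0.001)
})

test_that("successive group priors are exact multiples of R", {
  for (R in c(1.5, 2, 5)) {
    pr <- solve_delta_linear(casp8_n, 0.4, R)
    expect_equal(pr$delta[-1] / pr$delta[-4], rep(R, 3))
    pe <- solve_delta_exact(casp8_n, 0.4, R)
    expect_equal(pe$delta[-1] / pe$delta[-4], rep(R, 3))
  }
  pe <- solve_delta_exact(elicitation_spec(c(50, 30, 20), 0.5, c(2, 7)))
  expect_equal(pe$delta[2] / pe$delta[1], 2)
  expect_equal(pe$delta[3] / pe$delta[2], 7)
})

test_that("quadratic solver uses the printed coefficients and improves p0", {
  # root solves the printed polynomial exactly (independent polyroot check)
  n <- c(1698, 780, 362, 31); p0 <- 0.9; R <- 5
  pq <- solve_delta_quadratic(n, p0, R)
  aj <- n * R^(0:3)
  a <- sum(aj^2) + sum(outer(aj, aj)[upper.tri(diag(4))])
  b <- -sum(aj); c0 <- 1 - p0
  roots <- Re(polyroot(c(c0, b, a)))
  expect_equal(pq$delta[1], min(roots[roots > 0]), tolerance = 1e-12)
  expect_equal(a * pq$delta[1]^2 + b * pq$delta[1] + c0, 0, tolerance = 1e-12)
  # second-order correction brings the achieved p0 closer to the target
  pl <- solve_delta_linear(n, p0, R)
  expect_lt(abs(pq$achieved_p0 - p0), abs(pl$achieved_p0 - p0))
})

test_that("quadratic without real roots signals a typed condition", {
  # the flagship R = 5 spec is exactly the documented fallback situation
  expect_error(solve_delta_quadratic(casp8_n, 0.4, 5),
               class = "ebfine_no_real_root")
  pe <- tryCatch(solve_delta_quadratic(casp8_n, 0.4, 5),
                 ebfine_no_real_root = function(e) solve_delta_exact(casp8_n, 0.4, 5))
  expect_s3_class(pe, "group_priors")
  # p0 -> 1 limit: both roots collapse to zero
  pq <- solve_delta_quadratic(casp8_n, 1 - 1e-10, 5)
  expect_lt(pq$delta[1], 1e-12)
})

test_that("exact solver satisfies the product constraint to 1e-12", {
  set.seed(20)
  for (i in 1:25) {
    J <- sample(1:5, 1)
    n <- sample(1:3000, J)
    p0 <- runif(1, 0.05, 0.95)
    R <- runif(max(1, J - 1), 0.5, 8)
    pe <- solve_delta_exact(elicitation_spec(n, p0, R))
    expect_lt(abs(prod((1 - pe$delta)^n) - p0), 1e-12)
  }
  expect_equal(solve_delta_exact(c(1), 0.5, 2)$delta, 0.5)
})

test_that("exact and linear solutions agree in the p0 -> 1 limit", {
  rel <- vapply(c(0.9, 0.99, 0.999), function(p0) {
    e <- solve_delta_exact(casp8_n, p0, 5)$delta[1]
    l <- solve_delta_linear(casp8_n, p0, 5)$delta[1]
    abs(e - l) / l
  }, numeric(1))
  expect_true(all(diff(rel) < 0))
  expect_lt(rel[3], 1e-3)
})

test_that("linear first-order approximation misses p0 by the exp factor", {
  pl <- solve_delta_linear(casp8_n, 0.4, 5)
  expect_equal(pl$achieved_p0, exp(-0.6), tolerance = 1e-3)
  pe <- solve_delta_exact(casp8_n, 0.4, 5)
  expect_lt(abs(pe$achieved_p0 - 0.4), abs(pl$achieved_p0 - 0.4))
})

test_that("causal-count solver reduces to the linear one when p2 = 0", {
  pc <- solve_delta_causal_count(casp8_n, c(0.4, 1, 0), 5)
  pl <- solve_delta_linear(casp8_n, 0.4, 5)
  expect_equal(pc$delta, pl$delta, tolerance = 1e-14)
})

test_that("causal-count root matches a brute-force scan", {
  n <- c(12, 5); pm <- c(0.3, 0.5, 0.2); R <- 3
  pc <- solve_delta_causal_count(n, pm, R)
  rho <- c(1, 3)
  A <- sum(n * rho)
  B <- sum((n * rho)^2) + n[1] * n[2] * rho[1] * rho[2]
  f <- function(d) pm[1] + pm[2] * A * d + pm[3] * B * d^2 - 1
  grid <- seq(1e-8, 0.1, by = 1e-8)
  d_scan <- grid[which.min(abs(f(grid)))]
  expect_equal(pc$delta[1], d_scan, tolerance = 1e-7)
  expect_equal(f(pc$delta[1]), 0, tolerance = 1e-12)
})

test_that("scaling group sizes by k divides the causal-count root by k", {
  n <- c(40, 25, 10); pm <- c(0.3, 0.4, 0.3); R <- c(2, 4)
  d1 <- solve_delta_causal_count(n, pm, R)$delta[1]
  d5 <- solve_delta_causal_count(5 * n, pm, R)$delta[1]
  expect_equal(d5, d1 / 5, tolerance = 1e-12)
})

test_that("delta_1 is monotone in sizes, ratio and p0", {
  base <- solve_delta_linear(casp8_n, 0.4, 5)$delta[1]
  expect_lt(solve_delta_linear(casp8_n + c(500, 0, 0, 0), 0.4, 5)$delta[1], base)
  expect_lt(solve_delta_linear(casp8_n, 0.4, 6)$delta[1], base)
  expect_gt(solve_delta_linear(casp8_n, 0.3, 5)$delta[1], base)
  e_base <- solve_delta_exact(casp8_n, 0.4, 5)$delta[1]
  expect_lt(solve_delta_exact(casp8_n, 0.4, 6)$delta[1], e_base)
  expect_gt(solve_delta_exact(casp8_n, 0.3, 5)$delta[1], e_base)
})

test_that("approximation diagnostics report the constraint violation", {
  pl <- solve_delta_linear(casp8_n, 0.4, 5)
  d <- approximation_diagnostics(pl)
  expect_equal(d$achieved_p0, prod((1 - pl$delta)^casp8_n))
  expect_equal(d$n_delta, casp8_n * pl$delta)
  expect_equal(d$expansion_indicator, 5^(0:3) / casp8_n)
  expect_identical(d$worst_group, which.max(5^(0:3) / casp8_n))
  pe <- solve_delta_exact(casp8_n, 0.4, 5)
  expect_lt(approximation_diagnostics(pe)$abs_error, 1e-12)
})

test_that("decision tree maps extreme annotation profiles as designed", {
  ann <- data.frame(snp_id = c("a", "b", "c"),
                    regional_location = c(1, 0, 0),
                    histone_modification = c(1, 0, 1),
                    availability = c(1, 0, NA),
                    conservation = c(1, 0, NA))
  g <- assign_groups(ann)
  expect_identical(g$group[1], 4L)   # all evidence present
  expect_identical(g$group[2], 1L)   # no evidence at all
  # missing values are zeros: histone only, outside the gene -> group 2
  expect_identical(g$group[3], 2L)
  expect_identical(g$snp_id, c("a", "b", "c"))
})

test_that("unmapped combinations raise an error naming the combination", {
  rules <- data.frame(regional_location = 1L, histone_modification = 1L,
                      availability = NA, conservation = NA, group = 4L)
  ann <- data.frame(regional_location = 0, histone_modification = 1,
                    availability = 0, conservation = 0)
  expect_error(assign_groups(ann, rules), "regional_location=0")
  expect_error(assign_groups(ann[-1], rules), "lacks summary variable")
})

test_that("synthetic annotations round-trip through the default tree", {
  g0 <- annotate_snps(2871, c(1698, 780, 362, 31) / 2871, seed = 6)
  ann <- simulate_annotations(g0, missing_rate = 0.4, seed = 7)
  expect_true(anyNA(ann$conservation))        # masking actually happened
  g1 <- assign_groups(ann)
  expect_identical(g1$group, g0$group)
  expect_identical(g1$sizes, c(1698L, 780L, 362L, 31L))
})
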