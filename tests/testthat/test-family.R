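test_that("normalization constant matches closed forms and the exponential-integral oracle", {
  # beta = 0: power law on [1, Inf) has k = lambda exactly
  expect_identical(norm_const(0, 2), 2)
  expect_identical(abundance_dist(0, 0.7)$k, 0.7)
  # beta = 1: k = 1/(e^lam * E1(lam)), an exponential-integral identity
  skip_if_not_installed("pracma")
  for (lam in c(0.5, 1, 2)) {
    k_oracle <- 1 / (exp(lam) * pracma::expint(lam))
    expect_equal(norm_const(1, lam), k_oracle, tolerance = 1e-9,
                 info = paste("lam =", lam))
  }
  # intermediate beta against an independent quadrature engine
  expect_equal(norm_const(0.5, 1), oracle_norm(0.5, 1), tolerance = 1e-8)
})

test_that("non-integrable parameters raise an error naming the constraint", {
  expect_error(norm_const(0, -1), "lam > 0")
  expect_error(norm_const(1, 0), "total probability")
})

test_that("density integrates to one across the family", {
  pars <- param_pairs(50, seed = 424)
  for (i in seq_len(nrow(pars))) {
    d <- abundance_dist(pars$beta[i], pars$lam[i])
    # independent route: integrate the density itself on the n scale
    tot <- stats::integrate(function(n) dabund(n, d), 1, Inf,
                            rel.tol = 1e-11)$value
    expect_true(abs(tot - 1) < 1e-8,
                info = sprintf("beta=%.3f lam=%.3f tot=%.12f",
                               pars$beta[i], pars$lam[i], tot))
  }
})

test_that("density values match the printed endpoint forms", {
  d0 <- abundance_dist(0, 1)
  expect_equal(dabund(1, d0), 1, tolerance = 1e-14)
  expect_equal(dabund(10, d0), 0.01, tolerance = 1e-14)   # 1/n^2 Zipf density
  d1 <- abundance_dist(1, 0.5)
  expect_equal(dabund(3, d1), d1$k * (1 / 3) * exp(-1), tolerance = 1e-12)
})

test_that("log-density is exact and does not underflow", {
  d0 <- abundance_dist(0, 1)
  expect_equal(dabund(1, d0, log = TRUE), 0, tolerance = 1e-14)
  expect_equal(dabund(10, d0, log = TRUE), log(0.01), tolerance = 1e-12)
  grid <- c(1, 2, 10, 50)
  for (d in list(abundance_dist(0.5, 1.5), abundance_dist(1, 1))) {
    expect_equal(dabund(grid, d, log = TRUE), log(dabund(grid, d)),
                 tolerance = 1e-12)
  }
  lp <- dabund(1e6, abundance_dist(1, 1), log = TRUE)
  expect_true(is.finite(lp))
  expect_identical(exp(lp), 0)   # the density itself underflows; the log must not
})

test_that("cdf and survival are complementary with correct boundaries", {
  for (d in list(abundance_dist(0, 1.3), abundance_dist(1, 1),
                 abundance_dist(0.5, 0.7))) {
    expect_equal(pabund(1, d), 0, tolerance = 1e-14)
    expect_equal(sabund(1, d), 1, tolerance = 1e-10)
    n <- c(1.5, 2, 4, 10, 100)
    expect_equal(pabund(n, d) + sabund(n, d), rep(1, length(n)),
                 tolerance = 1e-10)
    expect_true(all(diff(sabund(n, d)) < 0))   # survival strictly decreasing
  }
  # closed-form Zipf survival n^-lambda
  expect_equal(sabund(4, abundance_dist(0, 1)), 0.25, tolerance = 1e-14)
  expect_equal(sabund(4, abundance_dist(0, 2)), 0.0625, tolerance = 1e-14)
})

test_that("density is strictly decreasing on the support", {
  n <- exp(seq(0, 8, length.out = 200))
  for (d in list(abundance_dist(0, 0.5), abundance_dist(0.3, 2),
                 abundance_dist(1, 0.1))) {
    expect_true(all(diff(dabund(n, d)) < 0))
  }
})

test_that("endpoint equivalence: tiny beta reproduces the pure power law", {
  lam <- 1.3
  d <- abundance_dist(1e-8, lam)
  n <- exp(seq(0, log(1e4), length.out = 60))
  ref <- lam * n^(-(1 + lam))
  expect_true(max(abs(dabund(n, d) - ref) / ref) < 1e-6)
})

test_that("endpoint equivalence: beta = 1 density is proportional to p^n / n", {
  lam <- 0.8
  p <- exp(-lam)
  d <- abundance_dist(1, lam)
  n <- 1:50
  ratio <- dabund(n, d) / (p^n / n)
  expect_true(max(abs(ratio / ratio[1] - 1)) < 1e-10)
})

test_that("mean abundance: closed forms, divergence state, and sampler cross-check", {
  expect_equal(mean_abundance(abundance_dist(0, 2)), 2, tolerance = 1e-12)
  expect_identical(mean_abundance(abundance_dist(0, 1)), Inf)   # Zipf's law
  expect_identical(mean_abundance(abundance_dist(0, 0.5)), Inf)
  # quadrature mean vs Monte-Carlo mean of the sampler
  d <- abundance_dist(1, 0.5)
  mu <- mean_abundance(d)
  x <- sample_abundance(d, 1e6, sampler_config(seed = 99))
  se <- stats::sd(x) / sqrt(length(x))
  expect_true(abs(mean(x) - mu) < 3 * se)
})

test_that("mean abundance is strictly decreasing in lambda at fixed beta", {
  for (beta in c(0.25, 1)) {
    mus <- vapply(c(0.3, 0.6, 1, 2, 4),
                  function(l) mean_abundance(abundance_dist(beta, l)),
                  numeric(1))
    expect_true(all(diff(mus) < 0))
  }
  mus0 <- vapply(c(1.2, 1.5, 2, 4),
                 function(l) mean_abundance(abundance_dist(0, l)), numeric(1))
  expect_true(all(diff(mus0) < 0))
})

test_that("solve_lambda inverts the mean constraint", {
  expect_equal(solve_lambda(0, 2), 2, tolerance = 1e-12)
  expect_equal(solve_lambda(0, 1e6), 1.000001, tolerance = 1e-9)
  expect_error(solve_lambda(0, 1), "> 1")
  expect_error(solve_lambda(0.5, 0.2), "> 1")
  # round trip for several betas, including the closed-form endpoint
  for (beta in c(0, 0.25, 0.5, 1)) {
    for (target in c(2, 5, 20)) {
      lam <- solve_lambda(beta, target)
      got <- mean_abundance(abundance_dist(beta, lam))
      expect_true(abs(got - target) / target < 1e-6,
                  info = sprintf("beta=%g target=%g got=%g", beta, target, got))
    }
  }
})

test_that("scale consistency links the log-density to the defining scale", {
  pars <- param_pairs(10, seed = 77, lam_range = c(0.3, 3))
  n <- c(1, 2, 7.5, 40, 500)
  for (i in seq_len(nrow(pars))) {
    d <- abundance_dist(pars$beta[i], pars$lam[i])
    lhs <- dabund(n, d) / d$k
    rhs <- exp(-d$lam * (scale_T_n(n, d$beta, d$lam) - log(n) / d$lam)) / n
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("process-scale and abundance-scale densities agree under the change of variable", {
  expect_true(change_of_variable_check(1, abundance_dist(1, 1)) < 1e-12)
  expect_true(change_of_variable_check(7.3, abundance_dist(0.5, 2)) < 1e-10)
  pars <- param_pairs(20, seed = 3131)
  grid <- c(1, 2, 5, 10, 100, 1e4)
  worst <- max(vapply(seq_len(nrow(pars)), function(i) {
    max(change_of_variable_check(grid, abundance_dist(pars$beta[i], pars$lam[i])))
  }, numeric(1)))
  expect_true(worst < 1e-9)
})

test_that("the density is invariant to affine transformations of its scale", {
  d <- abundance_dist(0.5, 1)
  expect_true(affine_invariance_check(d, 0, 1) < 1e-14)    # identity
  expect_true(affine_invariance_check(d, 3, 1) < 1e-10)    # pure shift
  expect_true(affine_invariance_check(d, 1.7, 2.5) < 1e-9) # shift + stretch
  expect_true(affine_invariance_check(abundance_dist(1, 0.5), -0.4, 0.3) < 1e-9)
  expect_error(affine_invariance_check(d, 1, 0), "b")
})

test_that("shifting the exponent offset is an affine transformation, not a new model", {
  # replacing (n - 1) by n in the beta = 1 exponent is the shift a = 1, b = 1
  d <- abundance_dist(1, 0.8)
  expect_true(affine_invariance_check(d, a = 1, b = 1) < 1e-10)
})

test_that("beta above one is allowed but flagged as beyond the continuum", {
  d <- abundance_dist(1.5, 1)
  expect_true(d$beyond_continuum)
  expect_false(abundance_dist(1, 1)$beyond_continuum)
  tot <- stats::integrate(function(n) dabund(n, d), 1, Inf, rel.tol = 1e-11)$value
  expect_equal(tot, 1, tolerance = 1e-8)
})
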