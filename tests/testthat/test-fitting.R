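test_that("rank assignment sorts descending with ordinal ranks under ties", {
  r <- rank_abundance(c(5, 1, 3))
  expect_equal(r$rank, 1:3)
  expect_equal(r$abundance, c(5, 3, 1))
  rt <- rank_abundance(c(2, 2, 2))
  expect_equal(rt$rank, 1:3)
  expect_equal(rt$abundance, rep(2, 3))
  # constructed inverse: descending input round(1000/s) gets back rank s
  n_s <- round(1000 / (1:100))
  rr <- rank_abundance(n_s)
  expect_equal(rr$abundance, n_s)   # stable ties preserve the constructed order
  expect_equal(rr$rank, 1:100)
  expect_error(rank_abundance(numeric(0)), "non-empty")
})

test_that("log-log regression recovers exact power-law slopes", {
  s <- 1:100
  f1 <- loglog_slope(rank_abundance(1000 / s))
  expect_equal(f1$slope, -1, tolerance = 1e-12)
  expect_true(f1$r_squared > 1 - 1e-12)
  # n_s = C/s^2  =>  log s = (log C - log n)/2, slope -1/2
  f2 <- loglog_slope(rank_abundance(1e6 / s^2))
  expect_equal(f2$slope, -0.5, tolerance = 1e-12)
  expect_error(loglog_slope(rank_abundance(c(3, 2, 1)), window = c(0, 0.1)),
               "distinct")
})

test_that("rank-size slope approximates -lambda for power-law members", {
  for (lam in c(0.8, 1.0, 1.5)) {
    x <- sample_abundance(abundance_dist(0, lam), 2e5,
                          sampler_config(seed = round(100 * lam)))
    sl <- loglog_slope(rank_abundance(x))$slope
    expect_true(abs(sl + lam) < 0.07,
                info = sprintf("lam=%g slope=%.4f", lam, sl))
  }
})

test_that("log-series rank curves bend away from a straight line on log-log axes", {
  # systematic convexity of OLS residuals separates the log series from Zipf
  x <- sample_logseries(0.95, 2e5, seed = 61)
  rk <- rank_abundance(x)
  first <- !duplicated(rk$abundance)
  s <- rk$rank[first]; n <- rk$abundance[first]
  fit <- stats::lm(log(s) ~ log(n))
  res <- stats::resid(fit)[order(n)]
  terc <- cut(seq_along(res), 3, labels = FALSE)
  mid <- mean(res[terc == 2]); outer <- mean(res[terc != 2])
  expect_true(sign(mid) != sign(outer))
})

test_that("profile MLE recovers generating parameters", {
  d <- abundance_dist(0.5, 1.5)
  x <- sample_abundance(d, 2e4, sampler_config(seed = 71))
  ft <- fit_mle(abundance_sample(x))
  expect_true(ft$converged)
  expect_true(abs(ft$beta_hat - 0.5) < 0.1)
  expect_true(abs(ft$lam_hat - 1.5) < 0.15)
  expect_true(is.finite(ft$se_beta) && is.finite(ft$se_lam))
})

test_that("fitted log-likelihood is recomputable and is a maximum", {
  x <- sample_abundance(abundance_dist(0.5, 1.5), 5e3, sampler_config(seed = 81))
  ft <- fit_mle(abundance_sample(x))
  dd <- abundance_dist(ft$beta_hat, ft$lam_hat)
  expect_equal(ft$loglik, sum(dabund(x, dd, log = TRUE)), tolerance = 1e-9)
  set.seed(82)
  for (i in 1:20) {
    b <- max(0, ft$beta_hat + stats::rnorm(1, 0, 0.2))
    l <- ft$lam_hat * exp(stats::rnorm(1, 0, 0.2))
    ll <- sum(dabund(x, abundance_dist(b, l), log = TRUE))
    expect_true(ll <= ft$loglik + 1e-6)
  }
})

test_that("exact discrete likelihood at the log-series endpoint recovers lambda = -log p", {
  p <- 0.7
  x <- sample_logseries(p, 2e4, seed = 91)
  ft <- fit_mle(abundance_sample(x), fix_beta = 1, discrete = TRUE)
  expect_identical(ft$likelihood, "discrete_logseries")
  expect_true(abs(ft$lam_hat - (-log(p))) < 3 * ft$se_lam)
  expect_equal(ft$loglik, sum(dlogseries(x, exp(-ft$lam_hat), log = TRUE)),
               tolerance = 1e-9)
  expect_error(fit_mle(abundance_sample(x), fix_beta = 0.5, discrete = TRUE),
               "fix_beta = 1")
  expect_error(fit_mle(abundance_sample(c(1.5, 2, 3)), fix_beta = 1,
                       discrete = TRUE), "integer")
})

test_that("estimator bias shrinks with sample size", {
  sizes <- c(1e3, 1e4, 1e5)
  med_err <- vapply(sizes, function(S) {
    errs <- vapply(1:11, function(s) {
      x <- sample_abundance(abundance_dist(0.5, 1.5), S,
                            sampler_config(seed = 7000 + 17 * s + S %% 1000))
      ft <- fit_mle(abundance_sample(x))
      abs(ft$beta_hat - 0.5) + abs(ft$lam_hat - 1.5)
    }, numeric(1))
    stats::median(errs)
  }, numeric(1))
  # monotone within Monte-Carlo noise: each decade shrinks the median error
  expect_true(med_err[2] < med_err[1])
  expect_true(med_err[3] < med_err[2])
})

test_that("endpoint selection is self-consistent on simulated data", {
  # discrete log-series data
  s1 <- select_endpoint(abundance_sample(sample_logseries(0.8, 1e4, seed = 101)))
  expect_true(s1$model_tag == "logseries_endpoint" || s1$indistinguishable)
  # Zipf data
  x2 <- sample_abundance(abundance_dist(0, 1), 1e4, sampler_config(seed = 102))
  s2 <- select_endpoint(abundance_sample(x2))
  expect_true(s2$model_tag == "zipf_endpoint" || s2$indistinguishable)
  # intermediate beta: the general model should win in a majority of seeds
  wins <- vapply(1:5, function(s) {
    x <- sample_abundance(abundance_dist(0.5, 1.5), 2e4,
                          sampler_config(seed = 200 + s))
    select_endpoint(abundance_sample(x))$model_tag == "general"
  }, logical(1))
  expect_true(sum(wins) >= 3)
  # bookkeeping: AIC = 2p - 2 loglik and LRT fields are present
  expect_equal(s2$table$aic, 2 * s2$table$n_par - 2 * s2$table$loglik)
  expect_equal(nrow(s2$lrt), 2L)
})

test_that("abundance samples are validated", {
  expect_error(abundance_sample(numeric(0)), "non-empty")
  expect_error(abundance_sample(c(1, 0.5)), ">= 1")
  expect_error(abundance_sample(c(1, NA)), ">= 1")
  expect_error(abundance_sample(1:3, labels = c("a", "a", "b")), "unique")
  expect_error(abundance_sample(1:3, labels = "a"), "length")
  expect_error(fit_mle(abundance_sample(c(0.2, 3))), ">= 1")
})
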