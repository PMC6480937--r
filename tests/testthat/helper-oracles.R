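# Independent oracles used across the suite.  These deliberately avoid the
# package's own numerical paths: series expansions, closed forms, and a
# different quadrature engine (pracma) stand against the implementation.

# Taylor-series oracle for (e^{bw} - 1)/b = sum_{k>=1} b^{k-1} w^k / k!
series_T <- function(w, beta, terms = 60) {
  acc <- 0
  term <- w              # k = 1 term
  for (k in seq_len(terms)) {
    acc <- acc + term
    term <- term * beta * w / (k + 1)
  }
  acc
}

# independent normalization integral on the log-abundance scale via pracma
oracle_norm <- function(beta, lam) {
  stopifnot(beta > 0)
  f <- function(u) exp(-lam * (exp(beta * u) - 1) / beta)
  1 / pracma::quadinf(f, 0, Inf, tol = 1e-12)$Q
}

# binomial 3-standard-error band for an empirical proportion
within_3se_prop <- function(phat, p, n) {
  abs(phat - p) <= 3 * sqrt(p * (1 - p) / n) + 1e-12
}

# draw reproducible (beta, lambda) parameter pairs for property sweeps
param_pairs <- function(n, seed, beta_range = c(0, 2), lam_range = c(0.2, 5)) {
  set.seed(seed)
  data.frame(beta = runif(n, beta_range[1], beta_range[2]),
             lam = runif(n, lam_range[1], lam_range[2]))
}
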