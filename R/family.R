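#' Construct a member of the abundance-distribution continuum
#'
#' Builds the continuous distribution on \eqn{n \in [1, \infty)} with density
#' \deqn{q(n) = k \, n^{-1} e^{-\lambda (n^\beta - 1)/\beta},}
#' the one-parameter family whose endpoints are Zipf's law
#' (\eqn{\beta \to 0}: \eqn{q(n) = \lambda n^{-(1+\lambda)}}) and the log
#' series (\eqn{\beta = 1}: \eqn{q(n) \propto p^n/n} with
#' \eqn{p = e^{-\lambda}}).  The normalization constant \eqn{k} is derived
#' state: it is recomputed here from \eqn{(\beta, \lambda)} so that total
#' probability is one, and is never user-settable.
#'
#' Values of `beta` above 1 are permitted numerically but lie outside the
#' Zipf--log-series continuum; the object records this in its
#' `beyond_continuum` field and the print method flags it.
#'
#' @param beta Curvature parameter, a single number >= 0.
#' @param lam Constraint multiplier \eqn{\lambda}, a single number > 0.
#'   Adjusts (via [solve_lambda()]) to meet a conserved mean abundance.
#' @return An object of class `"abundance_dist"`: a list with fields `beta`,
#'   `lam`, `k`, `log_k`, `beyond_continuum`.
#' @examples
#' d <- abundance_dist(beta = 1, lam = 1)
#' d$k  # 1 / (e * E1(1)) ~ 1.6769
#' @seealso [dabund()], [pabund()], [mean_abundance()], [solve_lambda()]
#' @export
abundance_dist <- function(beta, lam) {
  check_beta(beta)
  check_lam(lam)
  k <- norm_const(beta, lam)
  structure(
    list(beta = beta, lam = lam, k = k, log_k = log(k),
         beyond_continuum = beta > 1),
    class = "abundance_dist"
  )
}

#' @export
print.abundance_dist <- function(x, ...) {
  cat(sprintf("Abundance distribution: beta = %g, lambda = %g, k = %.8g\n",
              x$beta, x$lam, x$k))
  if (x$beta == 0) {
    cat(sprintf("  Zipf endpoint: q(n) = %g * n^-(1+%g) on [1, Inf)\n",
                x$lam, x$lam))
  } else if (x$beta == 1) {
    cat(sprintf("  Log-series endpoint: q(n) = k p^n / n with p = e^-lambda = %g\n",
                exp(-x$lam)))
  }
  if (isTRUE(x$beyond_continuum)) {
    cat("  Note: beta > 1 lies outside the Zipf <-> log-series continuum.\n")
  }
  invisible(x)
}

#' Normalization constant of a family member
#'
#' Computes \eqn{k} such that \eqn{\int_1^\infty k\, n^{-1}
#' e^{-\lambda (n^\beta - 1)/\beta}\, dn = 1}.  For \eqn{\beta = 0} the
#' closed form is \eqn{k = \lambda} (the power law \eqn{\lambda n^{-(1+\lambda)}}
#' on \eqn{[1,\infty)}); for \eqn{\beta > 0} the integral is computed by
#' adaptive quadrature after the substitution \eqn{u = \log n}, with a
#' tolerance-halving convergence check (relative accuracy ~1e-10).
#'
#' @param beta Curvature parameter >= 0.
#' @param lam Constraint multiplier > 0 (required for integrability at
#'   `beta = 0`).
#' @return The normalization constant `k > 0`.
#' @examples
#' norm_const(0, 2)  # exactly 2
#' norm_const(1, 1)  # 1/(e * E1(1)) ~ 1.6769
#' @export
norm_const <- function(beta, lam) {
  check_beta(beta)
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam)) {
    stop("`lam` must be a single finite number")
  }
  if (lam <= 0) {
    stop("non-integrable parameters: the density on [1, Inf) requires lam > 0 ",
         "(total probability cannot be one otherwise)")
  }
  if (beta == 0) {
    return(lam)
  }
  z <- .quad(function(u) exp(-lam * (expm1(beta * u) / beta)), 0, Inf,
             what = sprintf("normalization (beta=%g, lam=%g)", beta, lam))
  1 / z
}

#' Density of an abundance distribution
#'
#' Evaluates \eqn{q(n) = k\, n^{-1} e^{-\lambda (n^\beta - 1)/\beta}} (per
#' unit \eqn{n}).  With `log = TRUE` the log-density is computed directly as
#' \eqn{\log k - \log n - \lambda (n^\beta - 1)/\beta}, never by
#' exponentiating, so it stays finite far beyond the point where the density
#' itself underflows.
#'
#' @param n Numeric vector of abundances, each >= 1.
#' @param dist An [abundance_dist()] object.
#' @param log Logical; return the log-density?
#' @return Numeric vector of densities (or log-densities).
#' @examples
#' d0 <- abundance_dist(beta = 0, lam = 1)
#' dabund(10, d0)             # 0.01: the 1/n^2 Zipf density
#' dabund(1e6, abundance_dist(1, 1), log = TRUE)  # finite, ~ -1e6
#' @export
dabund <- function(n, dist, log = FALSE) {
  stopifnot(inherits(dist, "abundance_dist"))
  if (any(!is.finite(n)) || any(n < 1)) {
    stop("`n` must be finite and >= 1 (support of the abundance family)")
  }
  lp <- dist$log_k - base::log(n) - dist$lam * xbeta(n, dist$beta)
  if (log) lp else exp(lp)
}

#' Cumulative distribution and survival functions
#'
#' `pabund()` returns \eqn{P(N \le n)} and `sabund()` the survival
#' \eqn{P(N > n)}.  At the Zipf endpoint (`beta = 0`) the closed form
#' survival \eqn{n^{-\lambda}} is used; otherwise each is computed by
#' adaptive quadrature of the density on the log-abundance scale, so that
#' `pabund` is accurate near 0 and `sabund` near 0 independently.
#'
#' @inheritParams dabund
#' @return Numeric vector of probabilities; `pabund(1, dist)` is 0 and
#'   `sabund(1, dist)` is 1.
#' @examples
#' sabund(4, abundance_dist(0, 1))  # 0.25
#' @export
pabund <- function(n, dist) {
  stopifnot(inherits(dist, "abundance_dist"))
  if (any(!is.finite(n)) || any(n < 1)) {
    stop("`n` must be finite and >= 1 (support of the abundance family)")
  }
  if (dist$beta == 0) {
    return(1 - n^(-dist$lam))
  }
  f <- function(u) exp(-dist$lam * (expm1(dist$beta * u) / dist$beta))
  vapply(n, function(ni) {
    if (ni == 1) return(0)
    dist$k * .quad(f, 0, base::log(ni), what = "cdf")
  }, numeric(1))
}

#' @rdname pabund
#' @export
sabund <- function(n, dist) {
  stopifnot(inherits(dist, "abundance_dist"))
  if (any(!is.finite(n)) || any(n < 1)) {
    stop("`n` must be finite and >= 1 (support of the abundance family)")
  }
  if (dist$beta == 0) {
    return(n^(-dist$lam))
  }
  f <- function(u) exp(-dist$lam * (expm1(dist$beta * u) / dist$beta))
  vapply(n, function(ni) {
    dist$k * .quad(f, base::log(ni), Inf, what = "survival")
  }, numeric(1))
}

#' Mean abundance of a family member
#'
#' Computes \eqn{\langle n \rangle = \int_1^\infty n\, q(n)\, dn}.  At the
#' Zipf endpoint (`beta = 0`) the mean is \eqn{\lambda/(\lambda - 1)} for
#' \eqn{\lambda > 1} and diverges for \eqn{\lambda \le 1}; divergence is a
#' return value (`Inf`), not an error, so that Zipf's law
#' (\eqn{\lambda = 1}) remains a first-class family member.  For
#' \eqn{\beta > 0} the mean is always finite (the stretched-exponential tail
#' dominates any power) and is computed by quadrature on the log scale.
#'
#' @param dist An [abundance_dist()] object.
#' @return A single number, possibly `Inf`.
#' @examples
#' mean_abundance(abundance_dist(0, 2))  # 2
#' mean_abundance(abundance_dist(0, 1))  # Inf (Zipf's law)
#' @export
mean_abundance <- function(dist) {
  stopifnot(inherits(dist, "abundance_dist"))
  beta <- dist$beta; lam <- dist$lam
  if (beta == 0) {
    if (lam <= 1) return(Inf)
    return(lam / (lam - 1))
  }
  # E[n] = k * int_0^Inf exp(u - lam*(e^{beta u}-1)/beta) du
  z <- .quad(function(u) exp(u - lam * (expm1(beta * u) / beta)), 0, Inf,
             what = sprintf("mean (beta=%g, lam=%g)", beta, lam))
  dist$k * z
}

#' Solve the mean-abundance constraint for lambda
#'
#' Finds the multiplier \eqn{\lambda} at which the family member with the
#' given `beta` attains a conserved average abundance: the constraint that
#' defines \eqn{\lambda} in the theory.  At `beta = 0` the closed form is
#' \deqn{\lambda = \frac{1}{1 - 1/\langle n \rangle},}
#' so any large finite mean gives \eqn{\lambda \to 1} -- Zipf's law.  For
#' `beta > 0` the monotone map \eqn{\lambda \mapsto \langle n \rangle}
#' (strictly decreasing) is inverted by bracketed root finding.
#'
#' @param beta Curvature parameter >= 0.
#' @param mean_target Target mean abundance, > 1 (the support starts at 1).
#' @return The value of lambda matching the target mean to ~1e-8 relative.
#' @examples
#' solve_lambda(0, 2)    # 2
#' solve_lambda(0, 1e6)  # 1.000001: the Zipf limit
#' @export
solve_lambda <- function(beta, mean_target) {
  check_beta(beta)
  if (!is.numeric(mean_target) || length(mean_target) != 1L ||
      !is.finite(mean_target) || mean_target <= 1) {
    stop("`mean_target` must be a single finite number > 1 ",
         "(support starts at n = 1)")
  }
  if (beta == 0) {
    return(1 / (1 - 1 / mean_target))
  }
  g <- function(lam) mean_abundance(abundance_dist(beta, lam)) - mean_target
  # mean decreases in lambda: expand a geometric bracket around lam = 1
  lo <- 1; hi <- 1
  it <- 0L
  while (g(lo) < 0 && it < 60L) { lo <- lo / 4; it <- it + 1L }
  it <- 0L
  while (g(hi) > 0 && it < 60L) { hi <- hi * 4; it <- it + 1L }
  if (g(lo) < 0 || g(hi) > 0) {
    stop(sprintf(
      "could not bracket the root for mean %g at beta %g (tried lambda in [%g, %g])",
      mean_target, beta, lo, hi))
  }
  r <- stats::uniroot(g, c(lo, hi), tol = 1e-12 * max(1, lo))
  r$root
}

#' Change-of-variable consistency residual
#'
#' The family can be written on the process scale \eqn{r = \log n} as
#' \eqn{q_r(r) = k\, e^{-\lambda (e^{\beta r} - 1)/\beta}} or on the
#' abundance scale as \eqn{q_n(n) = k\, n^{-1} e^{-\lambda (n^\beta - 1)/\beta}};
#' the substitution \eqn{r \mapsto \log n}, \eqn{dr \mapsto n^{-1} dn} maps
#' one to the other.  This check evaluates both sides from the same
#' \eqn{(\beta, \lambda, k)} and returns the absolute residual
#' \eqn{|q_r(\log n)/n - q_n(n)|}, which should be at machine-precision
#' level.
#'
#' @inheritParams dabund
#' @return Numeric vector of non-negative residuals.
#' @export
change_of_variable_check <- function(n, dist) {
  stopifnot(inherits(dist, "abundance_dist"))
  if (any(!is.finite(n)) || any(n < 1)) {
    stop("`n` must be finite and >= 1")
  }
  r <- base::log(n)
  q_r <- dist$k * exp(-dist$lam * generic_T(r, dist$beta))
  abs(q_r / n - dabund(n, dist))
}

#' Affine-invariance residual of the defining scale
#'
#' The probability pattern is invariant to an affine transformation of its
#' defining scale, \eqn{T \mapsto a + bT}: a shift is absorbed by the
#' normalization constant (\eqn{k = k_a e^{-\lambda a}}, conserved total
#' probability) and a stretch by the multiplier (\eqn{\lambda = \lambda_b b},
#' conserved average value).  This check rebuilds the density from the
#' transformed scale with \eqn{\lambda' = \lambda/b} and a renormalized
#' \eqn{k'}, and returns the maximum absolute difference from the original
#' density over an abundance grid.
#'
#' @param dist An [abundance_dist()] object.
#' @param a Shift, any real number.
#' @param b Stretch, > 0.
#' @param grid Abundances at which to compare (default spans 1 to 1e4).
#' @return The maximum absolute density difference over the grid.
#' @examples
#' d <- abundance_dist(0.5, 1)
#' affine_invariance_check(d, a = 3, b = 1)     # shift only: ~1e-16
#' affine_invariance_check(d, a = 1.7, b = 2.5) # shift + stretch: < 1e-9
#' @export
affine_invariance_check <- function(dist, a, b,
                                    grid = c(1, 1.5, 2, 5, 10, 50, 100, 1e3, 1e4)) {
  stopifnot(inherits(dist, "abundance_dist"))
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0) {
    stop("`b` must be a single finite number > 0")
  }
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a))
  beta <- dist$beta; lam2 <- dist$lam / b
  Tfun <- function(u) expm1_ratio(u, beta)
  # unnormalized transformed density on the log scale, exponent -lam'(a + b T)
  f <- function(u) exp(-lam2 * (a + b * Tfun(u)))
  z <- .quad(f, 0, Inf, what = "affine renormalization")
  k2 <- 1 / z
  q2 <- k2 * f(base::log(grid)) / grid
  max(abs(q2 - dabund(grid, dist)))
}

# (e^{beta*u} - 1)/beta with the exact beta = 0 limit
expm1_ratio <- function(u, beta) {
  if (beta == 0) u else expm1(beta * u) / beta
}
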