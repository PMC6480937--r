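#' Generic affine-invariant scale function
#'
#' Evaluates the canonical one-parameter scale \eqn{T(w) = (e^{\beta w} - 1)/\beta},
#' the solution of the linear scaling differential equation that underlies the
#' abundance-distribution continuum.  As \eqn{\beta \to 0} the scale tends to
#' the identity, \eqn{T(w) \to w}; at \eqn{\beta = 1} it is \eqn{e^w - 1}.
#'
#' The implementation uses `expm1()` so that the evaluation is accurate to
#' relative machine precision uniformly in \eqn{\beta \ge 0}, including values
#' as small as `1e-300`; no explicit small-\eqn{\beta} series branch is needed,
#' and the function is continuous in \eqn{\beta} down to the exact
#' \eqn{\beta = 0} limit.
#'
#' @param w Numeric vector, the underlying (process-scale) variable.
#' @param beta Single non-negative number, the curvature parameter.
#' @return Numeric vector of the same length as `w`.
#' @examples
#' generic_T(1, 2)        # (e^2 - 1)/2
#' generic_T(1.5, 1e-10)  # ~ 1.5 (identity limit)
#' @export
generic_T <- function(w, beta) {
  stopifnot(is.numeric(w), all(is.finite(w)))
  check_beta(beta)
  if (beta == 0) {
    w
  } else {
    expm1(beta * w) / beta
  }
}

#' Power-scale helper (n^beta - 1)/beta
#'
#' The abundance-scale counterpart of [generic_T()], obtained by setting
#' \eqn{w = \log n}.  Tends to \eqn{\log n} as \eqn{\beta \to 0}.
#' Internal workhorse for densities and scales; vectorized in `n`.
#'
#' @param n abundances, all >= 1 (not checked here)
#' @param beta curvature parameter >= 0
#' @noRd
xbeta <- function(n, beta) {
  if (beta == 0) {
    log(n)
  } else {
    expm1(beta * log(n)) / beta
  }
}

#' Affine-invariant scale of the abundance continuum
#'
#' Evaluates the defining scale of the family,
#' \deqn{T_n = \frac{\log n}{\lambda} + \frac{n^\beta - 1}{\beta},}
#' which combines the logarithmic (process) component with the power-curvature
#' component.  At the Zipf endpoint (\eqn{\beta \to 0}) with \eqn{\lambda = 1}
#' the scale becomes \eqn{2 \log n}; at the log-series endpoint
#' (\eqn{\beta = 1}) it is \eqn{\log(n)/\lambda + n - 1}, logarithmic at small
#' abundance and linear at large abundance.
#'
#' @param n Numeric vector of abundances, each >= 1.
#' @param beta Single non-negative number, the curvature parameter.
#' @param lam Single positive number, the constraint multiplier.
#' @return Numeric vector: the scale value, 0 at `n = 1`.
#' @examples
#' scale_T_n(exp(1), beta = 1e-12, lam = 1)  # ~ 2: Zipf endpoint scale 2 log n
#' scale_T_n(3, beta = 1, lam = 2)           # log(3)/2 + 2
#' @export
scale_T_n <- function(n, beta, lam) {
  stopifnot(is.numeric(n))
  if (any(!is.finite(n)) || any(n < 1)) {
    stop("`n` must be finite and >= 1 (support of the abundance family)")
  }
  check_beta(beta)
  check_lam(lam)
  log(n) / lam + xbeta(n, beta)
}

check_beta <- function(beta) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta < 0) {
    stop("`beta` must be a single finite number >= 0")
  }
  invisible(beta)
}

check_lam <- function(lam) {
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam <= 0) {
    stop("`lam` must be a single finite number > 0")
  }
  invisible(lam)
}
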