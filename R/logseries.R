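#' Discrete log-series distribution
#'
#' Probability mass function of Fisher's log series on the positive integers,
#' \deqn{q_n = k\, p^n / n, \qquad k = -1/\log(1 - p),}
#' the classical species-abundance distribution.  It is the exact discrete
#' counterpart of the continuum's \eqn{\beta = 1} endpoint, with the link
#' \eqn{p = e^{-\lambda}}.
#'
#' @param x Vector of positive integers (integer-valued numerics accepted).
#' @param p Single number in (0, 1).
#' @param log Logical; return log-probabilities?
#' @return Numeric vector of probabilities summing to one over
#'   \eqn{n = 1, 2, \dots}.
#' @examples
#' dlogseries(1, 0.5)          # 1/log(2) * 0.5 ~ 0.72135
#' logseries_mean(0.5)         # ~ 1.4427
#' @export
dlogseries <- function(x, p, log = FALSE) {
  check_p(p)
  if (any(!is.finite(x)) || any(x < 1) || any(x != floor(x))) {
    stop("`x` must be positive integers (log-series support is n = 1, 2, ...)")
  }
  lk <- -base::log(-log1p(-p))    # log k, k = -1/log(1-p)
  lp <- lk + x * base::log(p) - base::log(x)
  if (log) lp else exp(lp)
}

#' @rdname dlogseries
#' @export
logseries_mean <- function(p) {
  check_p(p)
  # k * sum_n p^n = k p/(1-p)
  (-1 / log1p(-p)) * p / (1 - p)
}

#' Sample from the discrete log series
#'
#' Exact inverse-transform draws: the cumulative mass is tabulated until the
#' remaining tail is below 1e-15 and uniforms are mapped through the table.
#'
#' @param p Single number in (0, 1).
#' @param size Number of draws, >= 1.
#' @param seed Optional integer seed for reproducible streams.
#' @return Integer vector of `size` draws, each >= 1.
#' @examples
#' x <- sample_logseries(0.5, 1000, seed = 1)
#' mean(x == 1)  # ~ 0.72
#' @export
sample_logseries <- function(p, size, seed = NULL) {
  check_p(p)
  if (!is.numeric(size) || length(size) != 1L || size < 1 || size != floor(size)) {
    stop("`size` must be a single integer >= 1")
  }
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(size)
  k <- -1 / log1p(-p)
  # extend the pmf table until the un-tabulated tail is negligible;
  # geometric bound: tail after N  <  k p^{N+1} / ((N+1)(1-p))
  nmax <- 64L
  repeat {
    n <- seq_len(nmax)
    cum <- cumsum(k * p^n / n)
    tail_bound <- k * p^(nmax + 1) / ((nmax + 1) * (1 - p))
    if (tail_bound < 1e-15 || nmax > 2e7) break
    nmax <- nmax * 4L
  }
  draws <- findInterval(u, cum) + 1L
  draws[draws > nmax] <- nmax   # mass beyond the table < 1e-15
  as.integer(draws)
}

check_p <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1) {
    stop("`p` must be a single number strictly inside (0, 1)")
  }
  invisible(p)
}
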