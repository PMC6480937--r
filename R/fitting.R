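#' Construct an abundance sample
#'
#' A validated container for observed or simulated abundances: one count (>= 1)
#' per species or entity, with optional unique labels.
#'
#' @param values Numeric vector of abundances, each finite and >= 1.
#'   Integers are typical; real values are accepted (the family is
#'   continuous).
#' @param labels Optional character vector of entity identifiers, same
#'   length as `values`, unique.
#' @return An object of class `"abundance_sample"`.
#' @export
abundance_sample <- function(values, labels = NULL) {
  if (length(values) == 0L) stop("abundance sample must be non-empty")
  if (!is.numeric(values) || any(!is.finite(values)) || any(values < 1)) {
    stop("all abundances must be finite and >= 1")
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != length(values)) {
      stop("`labels` must have the same length as `values`")
    }
    if (anyDuplicated(labels)) stop("`labels` must be unique")
  }
  structure(list(values = as.numeric(values), labels = labels),
            class = "abundance_sample")
}

as_abundance_sample <- function(x) {
  if (inherits(x, "abundance_sample")) return(x)
  if (is.numeric(x)) return(abundance_sample(x))
  if (inherits(x, "synthetic_community")) return(abundance_sample(x$abundances))
  stop("cannot interpret input as an abundance sample")
}

#' @export
print.abundance_sample <- function(x, ...) {
  cat(sprintf("Abundance sample: %d entities, total %g, max %g\n",
              length(x$values), sum(x$values), max(x$values)))
  invisible(x)
}

#' Rank-abundance view of a sample
#'
#' Sorts abundances in descending order and assigns ordinal ranks
#' \eqn{s = 1, \dots, S}.  Ties keep their input order and still receive
#' distinct ordinal ranks: the rank-size convention indexes entities, not
#' abundance values.
#'
#' @param sample An [abundance_sample()], a bare numeric vector, or a
#'   synthetic community.
#' @return A data frame of class `"ranked_abundance"` with columns `rank`,
#'   `abundance`, and (if present) `label`.
#' @examples
#' rank_abundance(c(5, 1, 3))
#' @export
rank_abundance <- function(sample) {
  sample <- as_abundance_sample(sample)
  ord <- order(-sample$values)   # stable: ties keep input order
  out <- data.frame(rank = seq_along(ord), abundance = sample$values[ord])
  if (!is.null(sample$labels)) out$label <- sample$labels[ord]
  class(out) <- c("ranked_abundance", "data.frame")
  out
}

#' Log-log rank-abundance slope
#'
#' Ordinary least squares of \eqn{\log s} on \eqn{\log n} over the
#' rank-abundance curve: the classical Zipf diagnostic, whose slope is
#' \eqn{-1} for Zipf's law and, more generally, \eqn{-\lambda} for the
#' \eqn{\beta = 0} power-law member (survival \eqn{n^{-\lambda}} implies
#' rank proportional to \eqn{n^{-\lambda}}).
#'
#' Points are first deduplicated by abundance value, keeping the smallest
#' rank per value (tied entities would otherwise enter the regression as a
#' vertical run of points), and then restricted to abundances within the
#' stated sample quantiles.  The default window `c(0, 0.999)` drops the top
#' 0.1% of abundances, whose extreme order statistics are noisy and
#' dominate an unweighted OLS fit.
#'
#' @param ranked A `"ranked_abundance"` object (or anything accepted by
#'   [rank_abundance()]).
#' @param window Length-2 numeric, quantile bounds (lo, hi) on abundance.
#' @return An object of class `"loglog_fit"`: a list with `slope`, `se`,
#'   `intercept`, `r_squared`, `n_points`, `window`.
#' @examples
#' # exact inverse-rank data: slope -1
#' loglog_slope(rank_abundance(round(1000 / (1:100))))
#' @export
loglog_slope <- function(ranked, window = c(0, 0.999)) {
  if (!inherits(ranked, "ranked_abundance")) ranked <- rank_abundance(ranked)
  stopifnot(is.numeric(window), length(window) == 2L,
            window[1] >= 0, window[2] <= 1, window[1] < window[2])
  # smallest rank per distinct abundance value
  first <- !duplicated(ranked$abundance)
  s <- ranked$rank[first]
  n <- ranked$abundance[first]
  q <- stats::quantile(ranked$abundance, probs = window, names = FALSE)
  keep <- n >= q[1] & n <= q[2]
  if (sum(keep) < 3L) {
    stop("fewer than 3 distinct abundance values inside the quantile window")
  }
  fit <- stats::lm(log(s[keep]) ~ log(n[keep]))
  # summary.lm warns on exactly collinear (constructed power-law) input
  sm <- suppressWarnings(summary(fit))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 se = sm$coefficients[2, 2],
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 n_points = sum(keep),
                 window = window),
            class = "loglog_fit")
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf("Rank-abundance log-log regression (%d points, window %g-%g)\n",
              x$n_points, x$window[1], x$window[2]))
  cat(sprintf("  slope     %.6f  (SE %.4f)\n", x$slope, x$se))
  cat(sprintf("  intercept %.6f\n", x$intercept))
  cat(sprintf("  R-squared %.6f\n", x$r_squared))
  invisible(x)
}

# profile log-likelihood machinery ------------------------------------------

# log-likelihood of the sample at (beta, lam), up to no constants:
# sum log q(n_i) = N log k - sum log n_i - lam * sum xbeta(n_i)
.loglik_at <- function(beta, lam, n_obs, slog, sx) {
  n_obs * log(norm_const(beta, lam)) - slog - lam * sx
}

# maximize over lam at fixed beta; returns list(lam, loglik, at_bound)
.profile_lam <- function(beta, values, slog, lam_range) {
  n_obs <- length(values)
  sx <- sum(xbeta(values, beta))
  f <- function(t) .loglik_at(beta, exp(t), n_obs, slog, sx)
  opt <- stats::optimize(f, log(lam_range), maximum = TRUE, tol = 1e-9)
  span <- diff(log(lam_range))
  at_bound <- min(opt$maximum - log(lam_range[1]),
                  log(lam_range[2]) - opt$maximum) < 1e-4 * span
  list(lam = exp(opt$maximum), loglik = opt$objective, at_bound = at_bound)
}

#' Maximum-likelihood fit of the abundance continuum
#'
#' Estimates \eqn{(\beta, \lambda)} by maximizing the continuous
#' log-likelihood \eqn{\sum_i \log q(n_i)} with a profile search: a bounded
#' one-dimensional optimization over \eqn{\beta} in `beta_range`, with an
#' inner bounded search over \eqn{\lambda} (on the log scale) at each
#' \eqn{\beta}, the normalization constant recomputed per evaluation.  The
#' profile approach is robust on the likelihood ridge along which
#' \eqn{\beta} and \eqn{\lambda} trade off.  A flat or boundary-stuck
#' likelihood sets `converged = FALSE` rather than raising.
#'
#' The continuous likelihood is applied to integer counts directly, with no
#' continuity correction, and this approximation is accurate when counts are
#' not heaped near 1.  The one place an exact alternative exists is the
#' log-series endpoint: with `discrete = TRUE` (requires `fix_beta = 1` and
#' all-integer data) the exact discrete log-series likelihood
#' ([dlogseries()]) is maximized instead, which removes the discretization
#' bias in \eqn{\hat\lambda = -\log \hat p} for genuinely discrete
#' log-series count data.  Standard errors
#' come from the observed information (numerical curvature at the optimum)
#' and are `NA` when the estimate sits on a boundary.
#'
#' @param sample An [abundance_sample()] (or coercible input).
#' @param fix_beta Optional single value: fix \eqn{\beta} and estimate only
#'   \eqn{\lambda} (0 = Zipf endpoint, 1 = log-series endpoint).
#' @param beta_range Search interval for \eqn{\beta} (default `c(0, 2)`).
#' @param lam_range Search interval for \eqn{\lambda} (default
#'   `c(1e-4, 1e3)`).
#' @param discrete Use the exact discrete log-series likelihood?  Requires
#'   `fix_beta = 1` and integer data; default `FALSE` (continuous).
#' @return An object of class `"abund_fit"`: `beta_hat`, `lam_hat`,
#'   `loglik`, `n_obs`, `converged`, `model_tag`, `likelihood`
#'   (`"continuous"` or `"discrete_logseries"`), `se_beta`, `se_lam`.
#' @examples
#' x <- sample_abundance(abundance_dist(0, 1.5), 2000, sampler_config(seed = 1))
#' fit_mle(abundance_sample(x), fix_beta = 0)
#' @export
fit_mle <- function(sample, fix_beta = NULL,
                    beta_range = c(0, 2), lam_range = c(1e-4, 1e3),
                    discrete = FALSE) {
  sample <- as_abundance_sample(sample)
  values <- sample$values
  n_obs <- length(values)
  slog <- sum(log(values))

  if (isTRUE(discrete)) {
    if (is.null(fix_beta) || fix_beta != 1) {
      stop("the discrete log-series likelihood requires fix_beta = 1")
    }
    if (!all(values == floor(values))) {
      stop("the discrete log-series likelihood requires integer counts")
    }
    return(.fit_logseries_discrete(values, slog, lam_range, n_obs))
  }

  if (!is.null(fix_beta)) {
    check_beta(fix_beta)
    prof <- .profile_lam(fix_beta, values, slog, lam_range)
    beta_hat <- fix_beta
    lam_hat <- prof$lam
    converged <- !prof$at_bound && is.finite(prof$loglik)
    model_tag <- if (fix_beta == 0) "zipf_endpoint"
                 else if (fix_beta == 1) "logseries_endpoint"
                 else "fixed_beta"
    n_par <- 1L
  } else {
    pf <- function(beta) .profile_lam(beta, values, slog, lam_range)$loglik
    opt <- stats::optimize(pf, beta_range, maximum = TRUE, tol = 1e-6)
    beta_hat <- opt$maximum
    # a maximum within tol of the lower end is reported as the endpoint
    if (beta_hat - beta_range[1] < 1e-4) beta_hat <- beta_range[1]
    prof <- .profile_lam(beta_hat, values, slog, lam_range)
    lam_hat <- prof$lam
    converged <- !prof$at_bound && is.finite(prof$loglik)
    model_tag <- "general"
    n_par <- 2L
  }

  dist <- abundance_dist(beta_hat, lam_hat)
  loglik <- sum(dabund(values, dist, log = TRUE))
  if (!is.finite(loglik)) converged <- FALSE

  se <- .fit_se(beta_hat, lam_hat, values, slog, free_beta = is.null(fix_beta))
  structure(list(beta_hat = beta_hat, lam_hat = lam_hat, loglik = loglik,
                 n_obs = n_obs, converged = converged, model_tag = model_tag,
                 likelihood = "continuous",
                 n_par = n_par, se_beta = se$beta, se_lam = se$lam),
            class = "abund_fit")
}

# exact discrete log-series ML at the beta = 1 endpoint: p = e^{-lambda},
# ll(lambda) = N log k_d - lambda * sum(x) - sum(log x), k_d = -1/log(1-p)
.fit_logseries_discrete <- function(values, slog, lam_range, n_obs) {
  sx <- sum(values)
  ll <- function(lam) {
    p <- exp(-lam)
    -n_obs * log(-log1p(-p)) - lam * sx - slog
  }
  f <- function(t) ll(exp(t))
  opt <- stats::optimize(f, log(lam_range), maximum = TRUE, tol = 1e-10)
  lam_hat <- exp(opt$maximum)
  span <- diff(log(lam_range))
  at_bound <- min(opt$maximum - log(lam_range[1]),
                  log(lam_range[2]) - opt$maximum) < 1e-4 * span
  loglik <- sum(dlogseries(values, exp(-lam_hat), log = TRUE))
  hl <- 1e-5 * lam_hat
  d2 <- (ll(lam_hat + hl) - 2 * ll(lam_hat) + ll(lam_hat - hl)) / hl^2
  se_lam <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
  structure(list(beta_hat = 1, lam_hat = lam_hat, loglik = loglik,
                 n_obs = n_obs,
                 converged = !at_bound && is.finite(loglik),
                 model_tag = "logseries_endpoint",
                 likelihood = "discrete_logseries",
                 n_par = 1L, se_beta = NA_real_, se_lam = se_lam),
            class = "abund_fit")
}

# observed-information standard errors by central finite differences
.fit_se <- function(beta_hat, lam_hat, values, slog, free_beta) {
  n_obs <- length(values)
  ll <- function(beta, lam) {
    if (beta < 0 || lam <= 0) return(-Inf)
    .loglik_at(beta, lam, n_obs, slog, sum(xbeta(values, beta)))
  }
  hl <- 1e-4 * max(lam_hat, 1e-3)
  d2_lam <- (ll(beta_hat, lam_hat + hl) - 2 * ll(beta_hat, lam_hat) +
               ll(beta_hat, lam_hat - hl)) / hl^2
  if (!free_beta) {
    se_lam <- if (is.finite(d2_lam) && d2_lam < 0) sqrt(-1 / d2_lam) else NA_real_
    return(list(beta = NA_real_, lam = se_lam))
  }
  hb <- 1e-4
  if (beta_hat < 2 * hb) {
    # boundary estimate: curvature in beta is one-sided, SE not reported
    se_lam <- if (is.finite(d2_lam) && d2_lam < 0) sqrt(-1 / d2_lam) else NA_real_
    return(list(beta = NA_real_, lam = se_lam))
  }
  d2_beta <- (ll(beta_hat + hb, lam_hat) - 2 * ll(beta_hat, lam_hat) +
                ll(beta_hat - hb, lam_hat)) / hb^2
  d2_cross <- (ll(beta_hat + hb, lam_hat + hl) - ll(beta_hat + hb, lam_hat - hl) -
                 ll(beta_hat - hb, lam_hat + hl) + ll(beta_hat - hb, lam_hat - hl)) /
    (4 * hb * hl)
  info <- -matrix(c(d2_beta, d2_cross, d2_cross, d2_lam), 2, 2)
  cov <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(cov) || any(diag(cov) <= 0)) {
    return(list(beta = NA_real_, lam = NA_real_))
  }
  list(beta = sqrt(cov[1, 1]), lam = sqrt(cov[2, 2]))
}

#' @export
print.abund_fit <- function(x, ...) {
  cat(sprintf("Abundance-continuum ML fit (%s, %s likelihood), n = %d\n",
              x$model_tag, x$likelihood, x$n_obs))
  cat(sprintf("  beta   %.5f%s\n", x$beta_hat,
              if (is.na(x$se_beta)) "" else sprintf("  (SE %.4f)", x$se_beta)))
  cat(sprintf("  lambda %.5f%s\n", x$lam_hat,
              if (is.na(x$se_lam)) "" else sprintf("  (SE %.4f)", x$se_lam)))
  cat(sprintf("  log-likelihood %.4f   converged: %s\n",
              x$loglik, x$converged))
  invisible(x)
}

#' Endpoint model selection by AIC
#'
#' Fits the free-\eqn{\beta} model (2 parameters) and both endpoint models
#' -- Zipf (\eqn{\beta = 0}) and log series (\eqn{\beta = 1}), 1 parameter
#' each -- and compares them by AIC (\eqn{2p - 2\ell}).  Intermediate
#' \eqn{\beta} combines aspects of both endpoints, so the endpoints are not
#' nested in each other; AIC handles the mixed comparison, and
#' likelihood-ratio statistics are additionally reported for the nested
#' general-vs-endpoint pairs.  A winner within \eqn{\Delta}AIC < 2 of the
#' runner-up is flagged `indistinguishable`.
#'
#' Likelihoods entering the AIC must live on the same sample space.  For
#' all-integer data the log-series endpoint is fitted with its exact
#' discrete likelihood (see [fit_mle()]), and the continuous models
#' (general and Zipf) are evaluated -- at their continuous ML estimates --
#' by the probability mass each assigns to the round-half-up integer bins
#' \eqn{[1, 1.5), [1.5, 2.5), \dots}, which partition the support exactly.
#' Comparing a continuous density value against a discrete pmf would
#' otherwise be meaningless (densities exceed 1 near \eqn{n = 1}).  For
#' non-integer data all three models use the continuous likelihood
#' directly.  The `table$loglik` column holds the comparable
#' (AIC-entering) values; each fit object retains its own estimation
#' log-likelihood.
#'
#' @inheritParams fit_mle
#' @return An object of class `"endpoint_selection"`: the winning
#'   `model_tag`, a comparison `table`, the three `fits`, and the
#'   `indistinguishable` flag.
#' @export
select_endpoint <- function(sample, beta_range = c(0, 2),
                            lam_range = c(1e-4, 1e3)) {
  sample <- as_abundance_sample(sample)
  all_int <- all(sample$values == floor(sample$values))
  fits <- list(
    general            = fit_mle(sample, beta_range = beta_range, lam_range = lam_range),
    zipf_endpoint      = fit_mle(sample, fix_beta = 0, lam_range = lam_range),
    logseries_endpoint = fit_mle(sample, fix_beta = 1, lam_range = lam_range,
                                 discrete = all_int)
  )
  eval_ll <- vapply(fits, function(f) {
    if (all_int && f$likelihood == "continuous") {
      .bin_loglik(abundance_dist(f$beta_hat, f$lam_hat), sample$values)
    } else {
      f$loglik
    }
  }, numeric(1))
  tab <- data.frame(
    model = names(fits),
    beta = vapply(fits, function(f) f$beta_hat, numeric(1)),
    lambda = vapply(fits, function(f) f$lam_hat, numeric(1)),
    n_par = vapply(fits, function(f) f$n_par, integer(1)),
    loglik = eval_ll,
    row.names = NULL
  )
  tab$aic <- 2 * tab$n_par - 2 * tab$loglik
  tab$delta_aic <- tab$aic - min(tab$aic)
  ord <- order(tab$aic)
  winner <- tab$model[ord[1]]
  indistinct <- tab$aic[ord[2]] - tab$aic[ord[1]] < 2
  lrt <- data.frame(
    comparison = c("general_vs_zipf", "general_vs_logseries"),
    statistic = c(2 * (tab$loglik[1] - tab$loglik[2]),
                  2 * (tab$loglik[1] - tab$loglik[3])),
    df = 1L
  )
  lrt$p_value <- stats::pchisq(pmax(lrt$statistic, 0), df = 1, lower.tail = FALSE)
  structure(list(model_tag = winner, indistinguishable = indistinct,
                 table = tab, lrt = lrt, fits = fits),
            class = "endpoint_selection")
}

# log-likelihood of integer counts under the round-half-up binning
# [1, 1.5), [1.5, 2.5), ... of a continuous family member
.bin_loglik <- function(dist, values) {
  uv <- sort(unique(values))
  counts <- tabulate(match(values, uv))
  beta <- dist$beta; lam <- dist$lam
  mass <- vapply(uv, function(n) {
    lo <- max(1, n - 0.5); hi <- n + 0.5
    if (beta == 0) {
      lo^(-lam) - hi^(-lam)
    } else {
      dist$k * .quad(function(u) exp(-lam * (expm1(beta * u) / beta)),
                     log(lo), log(hi), what = "bin mass")
    }
  }, numeric(1))
  sum(counts * log(pmax(mass, 1e-300)))
}

#' @export
print.endpoint_selection <- function(x, ...) {
  cat("Endpoint model selection (AIC)\n")
  print(x$table, digits = 6)
  cat(sprintf("Selected: %s%s\n", x$model_tag,
              if (x$indistinguishable) " (runner-up within 2 AIC: indistinguishable)" else ""))
  invisible(x)
}
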