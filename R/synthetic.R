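#' Proportional-growth process model
#'
#' Describes the accumulated intensity of proportional processes acting on
#' abundance: a process whose number of affected individuals scales with the
#' current abundance.  Starting from a single individual
#' (\eqn{n_0 = 1}), the accumulated intensity over a horizon \eqn{\tau},
#' \deqn{r = \int_0^\tau m(t)\, dt,}
#' gives the final abundance \eqn{n = e^r}, so \eqn{r = \log n} exactly.
#'
#' Three intensity specifications are supported, all integrable in closed
#' form (no quadrature inside a generator, so provenance stays exact):
#' \describe{
#'   \item{`constant`}{\eqn{m(t) = } `rate`, so \eqn{r = } `rate * tau`.}
#'   \item{`piecewise`}{piecewise-constant `rates` over consecutive
#'     intervals whose right endpoints are `times` (ending at `tau`);
#'     \eqn{r} is the exact sum of rate times width.}
#'   \item{`iid_normal`}{the horizon is split into `n_steps` equal intervals
#'     and the intensity on each is an independent Normal(`mean`, `sd`)
#'     value, so \eqn{r} is a sum of i.i.d. terms -- the classic route by
#'     which proportional growth makes \eqn{r} approximately normal and
#'     \eqn{n} approximately lognormal.}
#' }
#'
#' @param type One of `"constant"`, `"piecewise"`, `"iid_normal"`.
#' @param tau Total time horizon, > 0.
#' @param rate Intensity for `type = "constant"`.
#' @param times,rates Right endpoints and intensities for
#'   `type = "piecewise"`; `times` must be increasing and end at `tau`.
#' @param mean,sd,n_steps Parameters for `type = "iid_normal"`.
#' @return An object of class `"process_model"`.
#' @examples
#' run_process(process_model("constant", tau = 10, rate = 0.3), size = 1)
#' @export
process_model <- function(type = c("constant", "piecewise", "iid_normal"),
                          tau, rate = NULL, times = NULL, rates = NULL,
                          mean = 0, sd = 1, n_steps = 100L) {
  type <- match.arg(type)
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    stop("`tau` must be a single finite number > 0")
  }
  m <- switch(type,
    constant = {
      if (is.null(rate) || !is.finite(rate)) {
        stop("configuration error: `constant` process needs a finite `rate`")
      }
      list(rate = rate)
    },
    piecewise = {
      if (is.null(times) || is.null(rates) || length(times) != length(rates)) {
        stop("configuration error: `piecewise` needs matching `times` and `rates`")
      }
      if (any(diff(c(0, times)) <= 0) || abs(times[length(times)] - tau) > 1e-12) {
        stop("configuration error: `times` must be increasing and end at `tau`")
      }
      list(times = times, rates = rates)
    },
    iid_normal = {
      if (!is.finite(mean) || !is.finite(sd) || sd < 0 || n_steps < 1) {
        stop("configuration error: `iid_normal` needs finite mean, sd >= 0, n_steps >= 1")
      }
      list(mean = mean, sd = sd, n_steps = as.integer(n_steps))
    }
  )
  structure(c(list(type = type, tau = tau, n0 = 1), m),
            class = "process_model")
}

#' Run a proportional-growth process
#'
#' Integrates the intensity \eqn{m(t)} over \eqn{[0, \tau]} for each
#' replicate (exact piecewise integration, never quadrature) and returns the
#' accumulated process value \eqn{r} and the resulting abundance
#' \eqn{n = e^r}.
#'
#' @param model A [process_model()].
#' @param size Number of replicate histories.
#' @param seed Optional integer seed (only the `iid_normal` type is random).
#' @return A data frame with columns `r` and `n`, one row per replicate.
#' @export
run_process <- function(model, size, seed = NULL) {
  stopifnot(inherits(model, "process_model"))
  if (!is.numeric(size) || length(size) != 1L || size < 1 || size != floor(size)) {
    stop("`size` must be a single integer >= 1")
  }
  if (!is.null(seed)) set.seed(seed)
  r <- switch(model$type,
    constant = rep(model$rate * model$tau, size),
    piecewise = {
      widths <- diff(c(0, model$times))
      rep(sum(model$rates * widths), size)
    },
    iid_normal = {
      dt <- model$tau / model$n_steps
      m <- matrix(stats::rnorm(size * model$n_steps, model$mean, model$sd),
                  nrow = model$n_steps)
      colSums(m) * dt
    }
  )
  data.frame(r = r, n = exp(r))
}

#' Generate a synthetic community
#'
#' Draws `n_species` abundances from the continuum member with the given
#' `beta` and either an explicit `lam` or a target `mean` abundance (in
#' which case [solve_lambda()] is invoked), then discretizes to integer
#' counts.  The provenance record -- parameters, seed, discretization rule,
#' package version -- is sufficient to regenerate the community
#' bit-identically.
#'
#' Discretization rules: `round_half_up` (`floor(x + 0.5)`, the default,
#' approximately unbiased) or `ceiling` (every partially present species
#' counts as at least one whole individual).  Both keep counts >= 1.
#'
#' @param beta Curvature parameter >= 0.
#' @param lam Constraint multiplier > 0 (give `lam` or `mean`, not both).
#' @param mean Target mean abundance > 1.
#' @param n_species Number of species (draws), >= 1.
#' @param seed Optional integer seed.
#' @param discretization `"round_half_up"` or `"ceiling"`.
#' @return An object of class `"synthetic_community"`: integer `abundances`
#'   and a `provenance` list.
#' @examples
#' cm <- make_community(beta = 1, mean = 3, n_species = 500, seed = 7)
#' mean(cm$abundances)
#' @export
make_community <- function(beta, lam = NULL, mean = NULL, n_species,
                           seed = NULL,
                           discretization = c("round_half_up", "ceiling")) {
  discretization <- match.arg(discretization)
  if (is.null(lam) == is.null(mean)) {
    stop("give exactly one of `lam` or `mean`")
  }
  if (is.null(lam)) lam <- solve_lambda(beta, mean)
  dist <- abundance_dist(beta, lam)
  x <- sample_abundance(dist, n_species, sampler_config(seed = seed))
  counts <- switch(discretization,
                   round_half_up = pmax(1, floor(x + 0.5)),
                   ceiling = ceiling(x))
  structure(
    list(abundances = as.integer(pmin(counts, .Machine$integer.max)),
         provenance = list(generator = "abundance_family",
                           beta = beta, lam = lam, mean_target = mean,
                           n_species = as.integer(n_species), seed = seed,
                           discretization = discretization,
                           tail_mass = attr(x, "tail_mass"),
                           package_version = as.character(utils::packageVersion("betasad")))),
    class = "synthetic_community"
  )
}

#' @export
print.synthetic_community <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("Synthetic community: %d species (beta = %s, lambda = %s, seed = %s)\n",
              length(x$abundances),
              format(p$beta), format(p$lam),
              if (is.null(p$seed)) "none" else format(p$seed)))
  invisible(x)
}

#' Write a fixed suite of seeded fixture communities
#'
#' Generates a small standard set of communities covering both endpoints and
#' an intermediate member -- Zipf (`beta = 0`, `lambda = 1`), the exact
#' discrete log series (`p = 0.8`), and `beta = 0.5` (`lambda = 1.5`) -- at
#' 100 and 10,000 species each, writes them as two-column TSV files
#' (`species<TAB>abundance`, with header), and records a JSON manifest with
#' full provenance.  Fixed seeds make regeneration byte-identical.
#'
#' @param out_dir Directory to write into (created if missing).
#' @return Invisibly, the manifest as a list (also written to
#'   `manifest.json`).
#' @export
make_fixture_suite <- function(out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      stop(sprintf("cannot create fixture directory '%s'", out_dir))
    }
  }
  specs <- list(
    list(name = "zipf",      beta = 0,   lam = 1,   p = NULL, seed = 101L),
    list(name = "logseries", beta = 1,   lam = NULL, p = 0.8, seed = 102L),
    list(name = "beta05",    beta = 0.5, lam = 1.5, p = NULL, seed = 103L)
  )
  sizes <- c(100L, 10000L)
  manifest <- list()
  for (sp in specs) {
    for (S in sizes) {
      file <- sprintf("%s_S%d.tsv", sp$name, S)
      path <- file.path(out_dir, file)
      if (!is.null(sp$p)) {
        counts <- sample_logseries(sp$p, S, seed = sp$seed + S)
        prov <- list(generator = "discrete_logseries", p = sp$p,
                     n_species = S, seed = sp$seed + S)
      } else {
        cm <- make_community(beta = sp$beta, lam = sp$lam, n_species = S,
                             seed = sp$seed + S)
        counts <- cm$abundances
        prov <- cm$provenance
      }
      labels <- sprintf("sp%05d", seq_len(S))
      ok <- tryCatch({
        utils::write.table(
          data.frame(species = labels, abundance = counts),
          path, sep = "\t", quote = FALSE, row.names = FALSE)
        TRUE
      }, error = function(e) {
        stop(sprintf("failed to write fixture '%s': %s", path, conditionMessage(e)))
      })
      manifest[[file]] <- prov
    }
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
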