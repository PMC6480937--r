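# Adaptive quadrature with a tolerance-halving convergence check.
# All improper integrals over abundance n in [1, Inf) are computed after the
# substitution u = log n, which removes the 1/n Jacobian and turns the
# integrands into smooth, rapidly decaying functions of u on [0, Inf).

.quad <- function(f, lower, upper, rel.tol = 1e-10, what = "integral") {
  run <- function(tol) {
    stats::integrate(f, lower, upper,
                     rel.tol = tol, abs.tol = 0,
                     subdivisions = 500L, stop.on.error = FALSE)
  }
  v1 <- run(rel.tol)
  v2 <- run(rel.tol / 2)
  ok <- c("OK", "roundoff error was detected")
  if (!(v1$message %in% ok) || !(v2$message %in% ok)) {
    stop(sprintf("quadrature failed for %s: %s", what, v2$message))
  }
  if (abs(v1$value - v2$value) > 1e-8 * max(1, abs(v2$value))) {
    stop(sprintf("quadrature did not converge for %s (tolerance-halving check)",
                 what))
  }
  v2$value
}
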