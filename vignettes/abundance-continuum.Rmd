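---
title: "The abundance continuum: model, numerics, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The abundance continuum: model, numerics, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betasad)
```

## The model

`betasad` implements a one-parameter continuum of probability distributions
for abundances $n \ge 1$,

$$q(n) = k\, n^{-1} e^{-\lambda\,(n^\beta - 1)/\beta},$$

built from the generic exponential form $q = k\,e^{-\lambda T}$ with the
affine-invariant scale

$$T_n = \frac{\log n}{\lambda} + \frac{n^\beta - 1}{\beta}.$$

Two conservation laws shape the family.  Conserved total probability makes
the pattern invariant to a *shift* of the scale, $T \mapsto a + T$ (the
normalization constant absorbs it, $k = k_a e^{-\lambda a}$); a conserved
average abundance makes it invariant to a *stretch*, $T \mapsto bT$ (the
multiplier absorbs it, $\lambda = \lambda_b b$).  The package does not
derive this symbolically; it ships the invariances as executable checks,
`affine_invariance_check()` and `change_of_variable_check()`, which rebuild
the density from a transformed scale and measure the residual (required
below $10^{-9}$ in the tests).

The curvature parameter $\beta$ moves the family between two famous
endpoints:

* **$\beta \to 0$ (Zipf).**  $(n^\beta - 1)/\beta \to \log n$ and
  $q(n) = \lambda n^{-(1+\lambda)}$.  Constraining a large mean forces
  $\lambda = 1/(1 - 1/\langle n\rangle) \to 1$, the $1/n^2$ density whose
  log-rank vs log-abundance slope is $-1$.  At this endpoint the scale
  degenerates to $T_n = 2\log n$.
* **$\beta = 1$ (log series).**  $q(n) \propto p^n/n$ with
  $p = e^{-\lambda}$: logarithmic decline at small $n$, exponential cutoff
  at large $n$.  Its normalization has the closed form
  $k = 1/(e^{\lambda} E_1(\lambda))$ with $E_1$ the exponential integral,
  which the test suite uses as an independent oracle.

The abundance scale and the *process* scale $r = \log n$ carry the same
pattern: $r$ is the accumulated intensity of proportional processes,
$r = \int_0^\tau m(t)\,dt$ with $n_0 = 1$, and the substitution
$r \mapsto \log n$, $dr \mapsto n^{-1}dn$ maps the process-scale density
$q_r = k\,e^{-\lambda(e^{\beta r}-1)/\beta}$ onto $q(n)$.  Both scales are
exposed throughout (densities, samplers, the process simulator).

### Support: continuous with a discrete companion

The continuum is defined on *continuous* $n \in [1, \infty)$; every closed
form above holds exactly there.  Observed abundances are usually integers,
and the exact discrete log series ($q_n = k\,p^n/n$ on $n = 1, 2, \dots$,
$k = -1/\log(1-p)$) is provided as a separate, exact type
(`dlogseries()`, `sample_logseries()`) rather than pretending the continuum
and the discrete law are the same object.  How a continuous member should
be discretized at intermediate $\beta$ is genuinely underdetermined; the
package exposes the rounding rule instead of hiding it (see *Synthetic
data* below).

Values $\beta > 1$ are numerically fine (the density still normalizes) but
lie outside the Zipf–log-series continuum; `abundance_dist()` flags them
via `beyond_continuum` and permits them.

## Parameters at a glance

| Parameter | Meaning | Domain | Notes |
|---|---|---|---|
| $\beta$ | curvature of the defining scale | $\ge 0$, dimensionless | 0 = Zipf endpoint, 1 = log series |
| $\lambda$ | constraint multiplier | $> 0$, dimensionless | set directly or via `solve_lambda(beta, mean)` |
| $k$ | normalization | derived | cached in the object; never user-settable |
| $\langle n\rangle$ | conserved mean abundance | $> 1$ | finite for $\beta > 0$; at $\beta = 0$ requires $\lambda > 1$ |

Infinite mean is a *value*, not an error: `mean_abundance()` returns `Inf`
for $\beta = 0,\ \lambda \le 1$, so Zipf's law itself ($\lambda = 1$)
remains a first-class, sampleable member.

## Numerical design

**Scale evaluation.**  $(e^{\beta w} - 1)/\beta$ is computed as
`expm1(beta * w) / beta`, which is accurate to relative machine precision
uniformly in $\beta$, down to $10^{-300}$, with an exact branch at
$\beta = 0$.  A conventional alternative is to switch to a truncated series
below a small-$\beta$ threshold; `expm1` makes any threshold unnecessary
and removes the continuity seam a threshold would create.

**Quadrature.**  All improper integrals are computed after the substitution
$u = \log n$, which absorbs the $n^{-1}$ Jacobian and turns every integrand
into a smooth, rapidly decaying function on $[0, \infty)$.  Adaptive
quadrature (`stats::integrate`) runs at relative tolerance $10^{-10}$ and
again at half that tolerance; disagreement beyond $10^{-8}$ relative is an
error, not a warning.  Closed forms replace quadrature wherever they exist
($\beta = 0$ everywhere; the mean at $\beta = 0$).

**Offset convention.**  The exponent is implemented with the $-1$ shift,
$-\lambda(n^\beta - 1)/\beta$, so that $T_n(1) = 0$.  Dropping the shift
(using $n^\beta/\beta$) is the affine shift $a = 1/\beta$ of the same
pattern; the test suite checks this as an affine-invariance case rather
than maintaining a second code path.

**Sampling.**  At $\beta = 0$ inversion is exact:
$n = u^{-1/\lambda}$.  For $\beta > 0$ the CDF is tabulated on 4096 points
linear in $u = \log n$ up to a truncation point chosen so the remaining
tail mass is below $10^{-9}$ (auto-extended when the default `grid_max =
1e9` is not enough), calibrated against the quadrature total, and inverted
with a monotone Hyman spline.  Draws landing beyond the table (probability
equal to the recorded tail mass) are clamped to the truncation point; the
tail mass and the truncation point used are attached to every sample as
attributes — reported, never silently dropped.  Rejection sampling was
rejected as a design: near $\beta = 0$ the tails are too heavy for a
robust envelope, while tabulation error is controllable and measurable.

**Likelihood.**  `fit_mle()` maximizes the continuous log-likelihood by a
profile search: an outer bounded one-dimensional optimization over
$\beta \in [0, 2]$ and an inner bounded search over $\log \lambda$, with
$k$ recomputed per evaluation.  The profile structure is deliberate:
$\beta$ and $\lambda$ trade off along a likelihood ridge (larger $\beta$
with smaller $\lambda$ produces similar density shapes), where joint 2-D
quasi-Newton steps are fragile.  Standard errors come from the observed
information by central finite differences and are `NA` on a boundary
($\hat\beta = 0$).  A flat or boundary-stuck likelihood sets
`converged = FALSE` instead of raising.

**Integer data.**  The continuous likelihood is applied to integer counts
directly, with no continuity correction — an approximation that is good
when counts are not heaped near 1 and is documented as such.  The one
exactly solvable case is the log-series endpoint: `fit_mle(fix_beta = 1,
discrete = TRUE)` maximizes the exact discrete log-series likelihood, which
matters for strongly heaped data (at $p = 0.7$, roughly half the mass sits
on $n = 1$, and the continuous approximation biases
$\hat\lambda = -\log\hat p$ substantially).  The command-line `fit
--fix-beta 1` chooses the exact discrete likelihood automatically for
integer data (`--continuous` overrides) and logs the choice.

**Model selection.**  `select_endpoint()` compares Zipf ($\beta = 0$), log
series ($\beta = 1$), and free-$\beta$ fits by AIC ($2p - 2\ell$; the
endpoints are not nested in each other, so AIC carries the mixed
comparison, with likelihood-ratio statistics reported for the nested
pairs).  Likelihoods entering one AIC table must live on one sample space:
for all-integer data the log-series endpoint uses its exact discrete
likelihood, and the continuous models are evaluated by the probability mass
they give the round-half-up bins $[1, 1.5), [1.5, 2.5), \dots$ — an exact
partition of the support — at their continuous ML estimates.  Comparing a
density *value* with a pmf would be meaningless (the continuous density
exceeds 1 near $n = 1$ for $\lambda > 1$ and would spuriously dominate any
discrete model).  A winner within $\Delta\mathrm{AIC} < 2$ of the runner-up
is flagged indistinguishable rather than over-claimed.

**Rank regression.**  `loglog_slope()` regresses $\log s$ on $\log n$
after (a) deduplicating by abundance value, keeping the smallest rank per
value — ordinal ranks index entities, so tied counts would otherwise enter
as a vertical run of points — and (b) restricting to abundances within the
sample quantile window, default $(0, 0.999)$.  The window is a declared
convention, not part of the theory: the handful of largest order statistics
are extremely noisy and dominate an unweighted OLS fit; how far rank-size
linearity should extend in a finite sample is not something the theory
specifies.  The window is always reported with the result.

## Synthetic data: what it emulates and what it does not

`make_community()` draws abundances from a chosen family member (optionally
solving the mean constraint first) and discretizes with a stated rule —
`round_half_up` (default, approximately unbiased) or `ceiling` (any
partially present species counts as one individual) — recording full
provenance (parameters, seed, rule, version) so every community is
regenerable bit-identically.  `run_process()` generates proportional-growth
histories with exactly integrable intensities: constant, piecewise
constant, or i.i.d. normal increments (under which $r$ is exactly normal
and $n$ lognormal — the classic growth route to heavy tails).  The three
intensity families are illustrations of the process scale, not claims
about any particular ecosystem.

Passing tests on these communities shows that the estimators recover the
parameters of data *generated by the model itself* under clean i.i.d.
sampling.  Real abundance data additionally carry detection limits,
sampling effort variation, aggregation across habitats, and temporal
autocorrelation, none of which the generator emulates; a good fit of the
continuum to real data is evidence about shape, not a validation of any
growth mechanism.

## Problem sizes and tolerances used by the test suite

Analytic identities are checked at $10^{-8}$–$10^{-14}$; stochastic checks
use fixed seeds with 3-standard-error bands or Kolmogorov–Smirnov tests at
the 1% level (with an explicit family-wise allowance when twenty tests run
at once).  Sample sizes were chosen as the smallest that make each check
sharp: $2\times10^5$ draws for rank-slope anchors ($\pm 0.05$ around $-1$),
$2\times10^4$ for parameter recovery ($\pm 0.1$ on $\beta$, $\pm 0.15$ on
$\lambda$, in at least 4 of 5 seeds), $10^6$ for sampler-vs-quadrature
means, $10^3$–$10^5$ for the consistency (shrinking bias) sweep.  The full
suite runs in well under a minute.

## Known limitations

* The discrete↔continuous correspondence at intermediate $\beta$ is a
  convention (rounding rule), not a derived result; only the $\beta = 1$
  endpoint has an exact discrete companion.
* The continuous likelihood on heavily heaped integer data (mass
  concentrated at $n = 1$–3) is biased; use the discrete endpoint
  likelihood where it applies, or treat estimates as approximate.
* $\hat\beta$ and $\hat\lambda$ are correlated along the likelihood ridge;
  with small samples ($\lesssim 10^3$) interval estimates are wide and
  endpoint selection frequently returns "indistinguishable", which is the
  honest answer.
* Infinite-mean members cannot be mean-constrained, and moment diagnostics
  are meaningless for them; rank-based summaries (`loglog_slope()`) are the
  right tool there.
* No multivariate, temporal, or spatially explicit extensions; supports
  other than $[1, \infty)$ are out of scope.
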