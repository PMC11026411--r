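---
title: "Quantifying maternal investment by allometric scaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying maternal investment by allometric scaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The metric

Across mammals, the cumulative mass of a litter at weaning scales tightly
with adult body mass. `allomi` exploits that regularity to turn litter
weaning mass into a size-adjusted index of maternal investment:

MI = log10( observed litter weaning mass / predicted litter weaning mass ),

where the prediction comes from an allometric regression of log10 litter
weaning mass (`y`) on log10 adult mass (`x`) and, optionally, log10
investment duration (`z`, gestation plus lactation, in days). MI is unitless:
0 means "exactly what an average mammal of that size (and investment
duration) achieves", +1 means ten times that, and on the log scale MI is
simply the vertical residual of the regression. A well-known methodological
relative is the encephalization quotient, which is likewise an allometric
residual.

Because MI is a residual, MI values are only comparable when they come from
the same fitted model; the package enforces this with a `fit_id` carried by
every MI table.

## The six estimators

The allometric line can be fitted in several defensible ways, and the
package implements the six used in the mammalian analysis this package
operationalises:

* **SLR** — ordinary least squares of `y` on `x`.
* **MSLR** — ordinary least squares of `y` on `x` and `z`.
* **SMA**, **MA** — standardised major axis and major axis, which attribute
  error to both axes. Closed forms: `b_SMA = sign(s_xy) * s_y / s_x`,
  `b_MA` from the leading principal axis of the 2x2 covariance.
* **PLMM**, **MPLMM** — heteroscedastic phylogenetic linear mixed models,
  the package's centrepiece:

  * mean model: `y_i = a + b x_i (+ c z_i) + r_i + e_i`, where the species
    random effects `r` are jointly Gaussian with covariance
    `lambda * rho(Lambda)`; `rho` is the Brownian-motion correlation implied
    by the phylogeny and `Lambda` (Pagel's lambda in `[0, 1]`) multiplies
    its off-diagonal entries, interpolating between a star phylogeny and
    full Brownian correlation;
  * dispersion model: `e_i ~ N(0, phi_i)` with
    `log(phi_i) = delta0 + delta1 * x_i + s_i` and `s_i ~ N(0, gamma)`
    independent across species. The residual variance therefore grows (or
    shrinks) log-linearly with adult mass and carries its own species-level
    random effect — a double hierarchical model.

  The dispersion linear predictor is on the natural-log variance scale;
  all analysis variables are log10. The two scales are never mixed.

MI is always computed from **marginal** predictions (fixed effects only,
random effects at their zero expectation). Conditional predictions — which
add the predicted `r_i` — would subtract exactly the phylogenetically
correlated ecology the metric is meant to capture; they are exposed via
`predict(fit, type = "conditional")` for diagnostics only.

## Fitting algorithm for the mixed models

The package fits the double hierarchical model by the standard alternating
(h-likelihood style) scheme:

1. *Mean step.* Given the current per-species variances `phi`, the
   phylogenetic random effect integrates out exactly, so `beta` is
   generalised least squares and `lambda` maximises the exact Gaussian
   marginal likelihood by a one-dimensional search.
2. *Dispersion step.* The squared conditional residuals, divided by their
   leverages so that their conditional expectation is `phi_i`, are Gamma
   responses with shape 1/2 (`phi * chi-squared_1`). The dispersion
   parameters `(delta0, delta1, gamma)` maximise the exact marginal
   likelihood of this Gamma mixture — the scalar random effect integrates
   by 25-node Gauss-Hermite quadrature — and `s` is set to its conditional
   mode.

The two steps iterate until the joint criterion changes by less than 1e-6
(relative), with a cap of 200 sweeps. Pagel's `Lambda` is profiled on
`[0, 1]` by an outer one-dimensional optimisation (`profile_pagel()` exposes
the profile and its likelihood-drop confidence interval). The reported
log-likelihood is the marginal likelihood at the estimates, with the
dispersion random effect handled by a Laplace approximation around its
conditional mode; when `gamma = 0` this is exact and equals the direct GLS
likelihood, a property the test suite checks against an explicit matrix
oracle to 1e-6.

The leverage standardisation in step 2 matters. Naively maximising a joint
(Laplace) likelihood over per-observation variances lets the dispersion
model chase individual residuals — the fitted line migrates towards a
subset of points it fits exactly, a classic degenerate attractor of
heteroscedastic ML. During development we observed precisely this runaway on
small simulated datasets; the alternating scheme with leverage-corrected
Gamma responses is the established cure and is what the package ships.

Numerical choices: covariance diagonals receive a 1e-10 jitter before
Cholesky factorisation; the dispersion random-effect variance is capped at
`exp(3)` on the natural-log variance scale (far beyond any biological
heteroscedasticity, and the quadrature grid degrades beyond it); profile
evaluations of `Lambda` warm-start the alternating fit from the previous
evaluation, so the profile is reproducible but accurate only to the inner
convergence tolerance (~1e-4 log-likelihood units); `rho(Lambda) = Lambda * rho + (1 - Lambda) * I`
keeps the matrix positive semi-definite for any tree and any
`Lambda` in `[0, 1]`; boundary estimates (`lambda` or `gamma` below 1e-6,
`Lambda` within 0.005 of 0 or 1) are flagged, not errors; a star phylogeny
flags `Lambda` as unidentifiable; polytomies and zero-length branches are
accepted as-is; tip labels match after normalising case and
space/underscore.

`Lambda` is restricted to `[0, 1]`. The correlation-function implementation
the original analysis used permits small excursions outside this range, but
only `[0, 1]` guarantees positive semi-definiteness for arbitrary trees, so
the package fixes the domain there.

ML (not REML) is used throughout because fixed effects are compared by
likelihood-ratio tests. For nominal degrees of freedom the package counts
fixed effects plus variance parameters (`sigma` for OLS; `lambda`,
`delta0`, `delta1`, `gamma` for the mixed models) and does **not** count the
profiled `Lambda`; the single-predictor mixed model therefore has 3 more
nominal parameters than SLR. Since the chi-squared reference is dubious for
variance parameters either way, the p-values that matter come from the
parametric bootstrap (`bootstrap_lrt()`), which simulates the null fit,
refits both models and uses the `(1 + k)/(n + 1)` convention.

## Data cleaning rules

`clean_traits()` applies two consistency filters with strict
"more than 15%" thresholds, after any user-supplied corrections (the
mechanism for known data-entry errors, e.g. a sea-mammal mass recorded in
the wrong unit):

* rule A (`sex_mass`): the sex-agnostic default adult mass lies outside
  `[0.85 * min, 1.15 * max]` of the available sex-specific masses. The
  source phrasing is ambiguous; the package reads it as this symmetric
  interval, which catches data-entry errors in either direction. Evaluated
  only when a sex-specific mass exists.
* rule B (`weaning_mass`): per-offspring weaning mass exceeds 1.15 times
  the default adult mass.

A species excluded under rule A is not re-examined under rule B, so each
exclusion cites exactly one rule. Litter size may be fractional (species
means) and is never rounded; it is treated as per-litter. Missing values
drop a species from a particular analysis, not from the dataset, so subsets
with and without duration data are reproducible. Masses are grams, durations
days, logs base 10.

## The synthetic-data generator

`simulate_dataset()` draws data under the mixed model's own generative
equations, so every estimator can be validated without external data:
a pure-birth tree with depth normalised to 1; `x ~ Uniform(0.5, 8.5)` on the
log10-gram scale (shrew to whale); `z = 1.5 + 0.25 x + N(0, 0.1)` so
investment duration scales with adult mass; noise defaults
`delta0 = -2.5`, `delta1 = 0.1`, `gamma = 0.05`, `lambda = 0.05`,
`Lambda = 0.9`, chosen so that phylogenetic signal and heteroscedasticity
are both detectable at a couple of hundred species. Fixed-effect defaults
are the published two-predictor phylogenetic estimates (0.204, 0.836,
-0.199). One integer seed drives everything through a single RNG stream
consumed in a fixed, documented order (tree, `x`, `z`, `s`, `r`,
residuals), which gives byte-identical reproducibility.

What the generator does *not* emulate: taxonomically biased sampling,
measurement error in predictors, correlated missingness, or trait evolution
beyond the Pagel-scaled Brownian model. Passing recovery tests therefore
demonstrates that the estimators invert their own generative assumptions,
not that real mammalian data satisfy those assumptions.

A note on precision: in the two-predictor design the duration predictor is
nearly collinear with mass (`sd(z | x) = 0.1`), so the duration coefficient
is intrinsically noisy — its per-replicate sampling SD at 250 species is
about 0.22. Recovery means over 20 replicates consequently carry a
Monte-Carlo SE near 0.05, which the validation suite states explicitly
rather than hiding behind larger replicate counts.

## Problem sizes used by the validation suite

The packaged checks run at sizes chosen to exercise every code path while
staying desk-scale: OLS recovery uses 500 replicates of n = 738 (the size of
the published six-method comparison); mixed-model recovery uses 20
replicates of 250-tip trees; bootstrap calibration uses 200 datasets of
n = 300 with 199 bootstrap draws; oracle equivalence uses n <= 12 where an
explicit matrix inverse is trivially computable.

## Worked example

```{r example, eval = FALSE}
library(allomi)

sim <- simulate_dataset(sim_config(n_species = 120, seed = 7))
fit <- allometry(sim$table, "mplmm", tree = sim$tree)
summary(fit)

mi <- rank_species(maternal_investment(fit))
head(mi)

# group comparison on the MI values
grp <- rep(c("A", "B"), length.out = nrow(mi))
kruskal_wallis(mi$MI, grp)
```

## Known limitations

* The Gamma-mixture dispersion variance `gamma` is weakly identified with a
  single observation per species (the log chi-squared "noise" has variance
  ~4.9 against which `gamma` of order 0.05 must be detected); its estimate
  is reported but should be interpreted cautiously at small n.
* Bootstrap confidence intervals for the mixed models hold `Lambda` at its
  fitted value during refits; the interval for `Lambda` itself comes from
  the likelihood profile.
* SMA and MA are not likelihood-based; they are excluded from LRTs, and
  their parametric bootstrap uses Gaussian vertical residuals around the
  fitted line.
* MI inherits every bias of its inputs: measurement error in weaning mass
  or litter size lands directly in the metric.
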