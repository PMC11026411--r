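# allomi — allometric scaling and the maternal investment metric

`allomi` quantifies maternal investment in mammals. The idea: the cumulative
mass of a litter at weaning scales allometrically with adult body mass, so a
species' investment, corrected for size, is how far its litter weaning mass
sits above or below that scaling law:

```
MI = log10( m_lw / (a' * m_a^b [* d^c]) )
```

where `m_lw` is observed litter weaning mass (per-offspring weaning mass x
litter size, grams), `m_a` adult mass (grams), `d` investment duration
(gestation + lactation, days), and `a' = 10^a`, `b`, `c` come from a
regression on the log10-log10 scale. MI is unitless: 0 is "average for its
size and investment duration", +1 is ten times the expected litter mass,
and MI values are comparable only within a single fitted model (the package
enforces this through a fit identity attached to every result).

The package is for comparative biologists working with life-history tables
(Amniote-style CSVs) and a phylogeny (Newick). It provides:

* **Six fitting methods** behind one front-end, `allometry(table, method,
  tree)`: ordinary least squares with one (`slr`) or two (`mslr`)
  predictors, standardised major axis (`sma`), major axis (`ma`), and
  heteroscedastic phylogenetic linear mixed models (`plmm`, `mplmm`). The
  mixed models — the centrepiece — put a Pagel-scaled phylogenetic random
  effect in the mean model and give the residual variance its own
  log-linear model with a species-level random effect (a double
  hierarchical model), jointly fitted with Pagel's lambda profiled.
* **Trait-table cleaning** with the strict more-than-15% consistency
  filters and a correction hook for known data-entry errors
  (`read_traits()`, `clean_traits()`, `analysis_table()`).
* **MI computation and comparison**: `maternal_investment()`,
  `rank_species()`, `compare_mass_proxies()` (default vs female adult
  mass), `mi_formula()`.
* **Inference**: parametric-bootstrap confidence intervals and
  likelihood-ratio tests (`bootstrap_ci()`, `bootstrap_lrt()`), the
  likelihood profile for Pagel's lambda (`profile_pagel()`), and the
  nonparametric test suite used for group comparisons (Kruskal-Wallis,
  exact/asymptotic Wilcoxon-Mann-Whitney, exact Wilcoxon-Pratt signed
  rank, Quade).
* **A synthetic-data generator** (`sim_config()`, `simulate_dataset()`,
  `recovery_experiment()`) that draws trees and traits under the mixed
  model's own generative equations, so every estimator is testable without
  external data.
* **A pipeline and CLI**: `run_pipeline()` executes
  clean → derive → fit → MI → comparisons and writes plain CSV/TSV/JSON;
  `inst/cli/allomi.R` is a thin Rscript front-end
  (`Rscript inst/cli/allomi.R pipeline --traits t.csv --tree t.nwk ...`).

## Worked example

```r
library(allomi)

sim <- simulate_dataset(sim_config(n_species = 120, seed = 7))
fit <- allometry(sim$table, "mplmm", tree = sim$tree)
summary(fit)
#> Allometric fit (MPLMM), n = 120 species
#> Coefficients (log10 scale):
#> (Intercept)           x           z
#>      0.5899      0.8795     -0.3613
#> Pagel Lambda = 0.982, phylo var lambda = 0.02351, dispersion gamma = 7.929e-08
#> r-squared = 0.9547; mass proxy = default; fit id = mplmm-3dba557a
#> 95% confidence intervals:
#>               2.5 % 97.5 %
#> (Intercept) -0.4551 1.6349
#> x            0.7061 1.0529
#> z           -1.0434 0.3207
#> Dispersion model: log(phi) = -1.69 + -0.05862 * x + s, var(s) = 7.929e-08
#> log-likelihood = -58.281 (converged)
#> boundary estimate(s): gamma
#> Allometric form:  m_lw / (3.89 * m_a^0.879 * d^-0.361)

head(rank_species(maternal_investment(fit)), 3)
#>   species     observed    predicted        MI rank
#> 1   sp047 930393.26277 69151.049109 1.1288678    1
#> 2   sp011     53.31562     7.563403 0.8481372    2
#> 3   sp064  10494.54442  1535.864180 0.8346108    3
```

The fitted mass scaling (0.879) and duration scaling (-0.361) recover the
generative values (0.836, -0.199) to within their sampling noise — the
duration predictor is nearly collinear with mass, so its coefficient is the
noisy one (its 95% interval spans -1.04 to 0.32 at this n). The top-ranked
species' MI of 1.13 means its litter weaning mass is 10^1.13 ≈ 13 times
what the allometry predicts for its adult mass and investment duration,
and the boundary flag records that the dispersion random-effect variance
collapsed to zero on this draw.

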