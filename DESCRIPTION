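Package: allomi
Title: Allometric Scaling and the Maternal Investment Metric for Mammals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies maternal investment in mammals as the log10 ratio of a
    species' observed litter mass at weaning to the mass predicted from an
    allometric regression on adult mass (and, optionally, investment duration,
    i.e. gestation plus lactation). Provides six fitting methods on the
    log10-log10 scale: ordinary least squares with one or two predictors,
    standardised major axis, major axis, and heteroscedastic phylogenetic
    linear mixed models in which a Pagel-scaled phylogenetic random effect
    enters the mean model and the residual variance follows its own log-linear
    model with a species-level random effect (a double hierarchical model).
    Includes life-history table cleaning with consistency filters, parametric
    bootstrap confidence intervals and likelihood-ratio tests, nonparametric
    group comparisons, and a synthetic-data generator for validating every
    estimator without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
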