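#' Fit an allometric scaling model for litter weaning mass
#'
#' Front-end for the six regression methods used to scale litter mass at
#' weaning (`y`, log10 g) on adult mass (`x`, log10 g) and, for the
#' two-predictor methods, investment duration (`z`, log10 d):
#' \describe{
#'   \item{`"slr"`}{ordinary least squares, `y ~ x`;}
#'   \item{`"mslr"`}{ordinary least squares, `y ~ x + z`;}
#'   \item{`"sma"`}{standardised major axis, attributing error to both axes;}
#'   \item{`"ma"`}{major axis (first principal axis of the covariance);}
#'   \item{`"plmm"`}{heteroscedastic phylogenetic linear mixed model, `y ~ x`
#'     with a Pagel-scaled phylogenetic random effect and a log-linear
#'     residual-dispersion model (see [dhglm_loglik()] for the model);}
#'   \item{`"mplmm"`}{as `"plmm"` with `z` as a second fixed effect.}
#' }
#' The mixed models require `tree`; Pagel's Lambda is profiled over `[0, 1]`
#' by an outer one-dimensional optimisation unless `lambda_pagel` is fixed.
#'
#' @param data An [analysis_table()] (or any data.frame with columns
#'   `species`, `y`, `x` and, for two-predictor methods, `z`).
#' @param method One of `"slr"`, `"mslr"`, `"sma"`, `"ma"`, `"plmm"`,
#'   `"mplmm"`.
#' @param tree An `ape::phylo` tree covering all species (mixed methods only).
#' @param level Confidence level for closed-form intervals (default 0.95).
#' @param groups Optional name of a grouping column in `data` (e.g.
#'   `"subclass"`): adds treatment-coded group main effects and the requested
#'   slope interactions (OLS and mixed methods only).
#' @param interactions Which slopes get group-specific terms when `groups` is
#'   set: any of `"mass"`, `"duration"`.
#' @param min_group_n Minimum species per group when `groups` is set.
#' @param lambda_pagel Fix Pagel's Lambda instead of profiling (mixed methods).
#' @param control List of optimiser settings for the mixed methods; see
#'   [dhglm_control()].
#' @return An object of class `"allomfit"` (and `"allomfit_dhglm"` for the
#'   mixed methods): coefficients, residual/dispersion parameters, confidence
#'   intervals, fitted marginal values and residuals (the residuals are the
#'   per-species MI values), and a `fit_id` enforcing the single-fit
#'   comparability rule. Supports [coef()], [confint()], [predict()],
#'   [residuals()], [simulate()], [logLik()], [summary()] and [plot()].
#' @references The allometric back-transform is `m_lw = 10^a * m_a^b * d^c`
#'   with `a` the fitted intercept; see [allometric_form()].
#' @export
#' @examples
#' set.seed(1)
#' tab <- data.frame(species = paste0("s", 1:50),
#'                   x = runif(50, 1, 6))
#' tab$y <- -0.2 + 0.78 * tab$x + rnorm(50, 0, 0.2)
#' fit <- allometry(tab, "slr")
#' coef(fit)
#' allometric_form(fit)
allometry <- function(data,
                      method = c("slr", "mslr", "sma", "ma", "plmm", "mplmm"),
                      tree = NULL, level = 0.95,
                      groups = NULL, interactions = c("mass", "duration"),
                      min_group_n = 10L,
                      lambda_pagel = NULL, control = dhglm_control()) {
  method <- match.arg(method)
  proxy <- attr(data, "mass_proxy") %||% "default"
  data <- as.data.frame(data)
  needs_z <- method %in% c("mslr", "mplmm")
  req <- c("species", "y", "x", if (needs_z) "z")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols))
    stop_allomi(paste0("data lacks column(s): ", paste(missing_cols, collapse = ", ")),
                "allomi_validation_error")
  keep <- stats::complete.cases(data[, req, drop = FALSE])
  if (any(!keep)) {
    message(sum(!keep), " species dropped for missing analysis variables")
    data <- data[keep, , drop = FALSE]
  }
  if (!is.null(groups)) {
    if (!method %in% c("slr", "mslr", "plmm", "mplmm"))
      stop_allomi("group-specific slopes are not defined for SMA/MA fits",
                  "allomi_validation_error")
    if (!groups %in% names(data))
      stop_allomi(paste0("grouping column not found: ", groups),
                  "allomi_validation_error")
    data[[groups]] <- factor(data[[groups]])
    cnt <- table(data[[groups]])
    if (length(cnt) < 2L)
      stop_allomi("grouped fit needs at least two groups", "allomi_validation_error")
    small <- names(cnt)[cnt < min_group_n]
    if (length(small))
      stop_allomi(paste0("group(s) below the minimum of ", min_group_n,
                         " species: ", paste(small, collapse = ", ")),
                  "allomi_validation_error")
    if (length(interactions))
      interactions <- match.arg(interactions, several.ok = TRUE)
  }

  fit <- switch(method,
    slr   = fit_ols(data, duration = FALSE, level, groups, interactions),
    mslr  = fit_ols(data, duration = TRUE,  level, groups, interactions),
    sma   = fit_axis(data, kind = "sma", level),
    ma    = fit_axis(data, kind = "ma", level),
    plmm  = fit_dhglm(data, tree, duration = FALSE, level, groups,
                      interactions, lambda_pagel, control),
    mplmm = fit_dhglm(data, tree, duration = TRUE, level, groups,
                      interactions, lambda_pagel, control))

  fit$method <- method
  fit$proxy <- proxy
  fit$level <- level
  fit$data <- data
  fit$fit_id <- make_fit_id(method, proxy, data$species, fit$coefficients)
  class(fit) <- c(if (method %in% c("plmm", "mplmm")) "allomfit_dhglm",
                  "allomfit")
  fit
}

# ---- ordinary least squares (SLR / MSLR), delegated to stats::lm ----------

fit_ols <- function(data, duration, level, groups = NULL, interactions = NULL) {
  n <- nrow(data)
  if (n < (if (duration) 4L else 3L))
    stop_allomi("too few species for an OLS fit", "allomi_degenerate_design")
  if (stats::var(data$x) == 0)
    stop_allomi("adult mass is constant: degenerate design", "allomi_degenerate_design")
  if (duration) {
    cc <- if (stats::var(data$z) == 0) 1 else stats::cor(data$x, data$z)
    if (!is.finite(cc) || abs(cc) >= 1 - 1e-12)
      stop_allomi("adult mass and duration are collinear: degenerate design",
                  "allomi_degenerate_design")
  }
  fml <- ols_formula(duration, groups, interactions)
  lmfit <- stats::lm(fml, data = data)
  if (any(is.na(stats::coef(lmfit))))
    stop_allomi("rank-deficient design in OLS fit", "allomi_degenerate_design")
  e <- stats::residuals(lmfit)
  # summary.lm (also behind vcov/confint) warns on exact noiseless data;
  # exact recovery is a legitimate use here
  ci <- suppressWarnings(stats::confint(lmfit, level = level))
  r2 <- suppressWarnings(summary(lmfit)$r.squared)
  vc <- suppressWarnings(stats::vcov(lmfit))
  list(coefficients = stats::coef(lmfit),
       sigma = sqrt(mean(e^2)),
       n = n,
       df_residual = lmfit$df.residual,
       r_squared = r2,
       vcov = vc,
       ci = ci,
       fitted_marginal = as.numeric(stats::fitted(lmfit)),
       residuals = as.numeric(e),
       groups = groups, interactions = if (!is.null(groups)) interactions,
       formula = fml)
}

ols_formula <- function(duration, groups, interactions) {
  rhs <- "x"
  if (duration) rhs <- c(rhs, "z")
  if (!is.null(groups)) {
    rhs <- c(rhs, groups)
    if ("mass" %in% interactions) rhs <- c(rhs, paste0(groups, ":x"))
    if (duration && "duration" %in% interactions) rhs <- c(rhs, paste0(groups, ":z"))
  }
  stats::as.formula(paste("y ~", paste(rhs, collapse = " + ")))
}

# ---- standardised major axis and major axis -------------------------------

fit_axis <- function(data, kind, level) {
  n <- nrow(data)
  if (n < 3L) stop_allomi("too few species for an axis fit", "allomi_degenerate_design")
  x <- data$x; y <- data$y
  sx2 <- stats::var(x); sy2 <- stats::var(y); sxy <- stats::cov(x, y)
  if (sx2 == 0 || sy2 == 0)
    stop_allomi("zero variance in x or y: degenerate design", "allomi_degenerate_design")
  r <- sxy / sqrt(sx2 * sy2)
  if (sxy == 0)
    stop_allomi(if (kind == "sma") "zero covariance: SMA slope sign undefined"
                else "zero covariance: principal axis is vertical/horizontal",
                "allomi_degenerate_design")
  if (kind == "sma") {
    b <- sign(sxy) * sqrt(sy2 / sx2)
    # Warton et al. interval: b * (sqrt(B + 1) +/- sqrt(B))
    B <- stats::qf(level, 1, n - 2) * (1 - r^2) / (n - 2)
    ci_b <- sort(b * (sqrt(B + 1) + c(-1, 1) * sqrt(B)))
  } else {
    b <- (sy2 - sx2 + sqrt((sy2 - sx2)^2 + 4 * sxy^2)) / (2 * sxy)
    # large-sample principal-axis angle interval
    ev <- eigen(matrix(c(sx2, sxy, sxy, sy2), 2), symmetric = TRUE)$values
    theta <- atan(b)
    se_theta <- sqrt(ev[1] * ev[2] / ((n - 2) * (ev[1] - ev[2])^2))
    half <- atan(se_theta * sqrt(stats::qf(level, 1, n - 2)))
    ci_b <- sort(tan(theta + c(-1, 1) * half))
  }
  a <- mean(y) - b * mean(x)
  fitted <- a + b * x
  e <- y - fitted
  # intercept interval from the slope interval propagated through (xbar, ybar)
  ci_a <- sort(mean(y) - ci_b * mean(x))
  ci <- rbind("(Intercept)" = ci_a, x = ci_b)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2)), "%")
  list(coefficients = c("(Intercept)" = a, x = b),
       sigma = sqrt(mean(e^2)),
       n = n, df_residual = n - 2,
       r_squared = r^2,
       ci = ci,
       fitted_marginal = fitted,
       residuals = e,
       groups = NULL)
}

# ---- allometric (back-transformed) form -----------------------------------

#' Back-transform a fit to its allometric form
#'
#' Converts a log10-scale linear fit `y = a + b x (+ c z)` into the allometric
#' relationship `m_lw = a' * m_a^b (* d^c)` with `a' = 10^a`. Values are kept
#' at full precision; the print method rounds the constant to 3 significant
#' figures and the exponents to 3 decimals.
#'
#' @param fit An [allometry()] fit without group-specific terms.
#' @return Object of class `"allometric_form"` with fields `constant`,
#'   `exponent_mass`, `exponent_duration` (or `NA`), `method`, `fit_id`.
#' @export
allometric_form <- function(fit) {
  stopifnot(inherits(fit, "allomfit"))
  if (!is.null(fit$groups))
    stop_allomi("no single allometric form for a fit with group-specific slopes",
                "allomi_validation_error")
  cf <- fit$coefficients
  structure(list(constant = 10^unname(cf[["(Intercept)"]]),
                 exponent_mass = unname(cf[["x"]]),
                 exponent_duration = if ("z" %in% names(cf)) unname(cf[["z"]]) else NA_real_,
                 method = fit$method, fit_id = fit$fit_id),
            class = "allometric_form")
}

#' @export
print.allometric_form <- function(x, ...) {
  cat(format_mi_formula(x), "\n")
  invisible(x)
}

#' Predict litter mass at weaning from an allometric form
#'
#' @param object An [allometric_form()].
#' @param adult_mass Adult mass in grams (vectorised).
#' @param duration Investment duration in days; required iff the form has a
#'   duration exponent.
#' @param ... Unused.
#' @return Predicted litter mass at weaning in grams (strictly positive).
#' @export
predict.allometric_form <- function(object, adult_mass, duration = NULL, ...) {
  stopifnot(all(adult_mass > 0))
  out <- object$constant * adult_mass^object$exponent_mass
  if (!is.na(object$exponent_duration)) {
    if (is.null(duration))
      stop_allomi("this form includes investment duration: supply `duration`",
                  "allomi_validation_error")
    stopifnot(all(duration > 0))
    out <- out * duration^object$exponent_duration
  }
  out
}

# ---- standard S3 methods ---------------------------------------------------

#' @export
coef.allomfit <- function(object, ...) object$coefficients

#' @export
confint.allomfit <- function(object, parm, level, ...) object$ci

#' @export
fitted.allomfit <- function(object, ...) object$fitted_marginal

#' @export
residuals.allomfit <- function(object, ...) object$residuals

#' @export
nobs.allomfit <- function(object, ...) object$n

#' @export
logLik.allomfit <- function(object, ...) {
  if (object$method %in% c("sma", "ma"))
    stop_allomi("SMA/MA fits are not likelihood-based", "allomi_validation_error")
  n <- object$n
  p <- length(object$coefficients)
  ll <- -n / 2 * (log(2 * pi * object$sigma^2) + 1)
  structure(ll, df = p + 1L, nobs = n, class = "logLik")
}

#' Predict on the log10 or raw scale
#'
#' Marginal predictions use fixed effects only (random effects at their zero
#' expectation); these are the predictions the MI metric is scaled against.
#' Conditional predictions (mixed fits only, in-sample species) add the
#' predicted phylogenetic random effect and are exposed for diagnostics.
#'
#' @param object An [allometry()] fit.
#' @param newdata Data frame with columns `x` (and `z` for two-predictor
#'   fits, plus the grouping column for grouped fits); default: training data.
#' @param type `"marginal"` (default) or `"conditional"`.
#' @param scale `"log10"` (default) or `"response"` (grams).
#' @param ... Unused.
#' @export
predict.allomfit <- function(object, newdata = NULL,
                             type = c("marginal", "conditional"),
                             scale = c("log10", "response"), ...) {
  type <- match.arg(type)
  scale <- match.arg(scale)
  if (type == "conditional")
    stop_allomi("conditional predictions exist only for mixed-model fits",
                "allomi_validation_error")
  if (is.null(newdata)) {
    yhat <- object$fitted_marginal
  } else {
    yhat <- marginal_linear_predictor(object, newdata)
  }
  if (scale == "response") 10^yhat else yhat
}

marginal_linear_predictor <- function(object, newdata) {
  cf <- object$coefficients
  needs_z <- object$method %in% c("mslr", "mplmm")
  if (needs_z && !"z" %in% names(newdata))
    stop_allomi("this fit includes investment duration: newdata needs `z`",
                "allomi_validation_error")
  if (is.null(object$groups)) {
    yhat <- cf[["(Intercept)"]] + cf[["x"]] * newdata$x
    if (needs_z) yhat <- yhat + cf[["z"]] * newdata$z
    return(as.numeric(yhat))
  }
  fml <- stats::as.formula(paste("~", paste(deparse(object$formula[[3]]), collapse = "")))
  newdata[[object$groups]] <- factor(newdata[[object$groups]],
                                     levels = levels(object$data[[object$groups]]))
  X <- stats::model.matrix(fml, newdata)
  as.numeric(X[, names(cf), drop = FALSE] %*% cf)
}

#' Simulate responses from a fitted allometric model
#'
#' Draws new log10 litter-mass vectors from the fitted generative model:
#' Gaussian vertical residuals around the fitted line for SLR/MSLR (SMA and MA
#' use the same vertical-residual form), and the full hierarchy (phylogenetic
#' random effect, dispersion random effect, heteroscedastic residual) for the
#' mixed fits. This is the engine behind [bootstrap_ci()] and
#' [bootstrap_lrt()].
#'
#' @param object An [allometry()] fit.
#' @param nsim Number of response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A numeric matrix, `n` rows by `nsim` columns.
#' @export
simulate.allomfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  mu <- object$fitted_marginal
  matrix(stats::rnorm(n * nsim, mean = mu, sd = object$sigma), n, nsim)
}

#' @export
print.allomfit <- function(x, digits = 4, ...) {
  cat(sprintf("Allometric fit (%s), n = %d species\n", toupper(x$method), x$n))
  cat("Coefficients (log10 scale):\n")
  print(round(x$coefficients, digits))
  if (inherits(x, "allomfit_dhglm")) {
    cat(sprintf("Pagel Lambda = %.3f, phylo var lambda = %.4g, dispersion gamma = %.4g\n",
                x$Lambda, x$lambda_phy, x$gamma_disp))
  } else {
    cat(sprintf("Residual SD = %.4f (log10 g)\n", x$sigma))
  }
  invisible(x)
}

#' @export
summary.allomfit <- function(object, ...) {
  structure(list(fit = object), class = "summary.allomfit")
}

#' @export
print.summary.allomfit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("r-squared = %.4f; mass proxy = %s; fit id = %s\n",
              f$r_squared, f$proxy, f$fit_id))
  cat(sprintf("%g%% confidence intervals:\n", 100 * f$level))
  print(round(f$ci, 4))
  if (inherits(f, "allomfit_dhglm")) {
    cat(sprintf("Dispersion model: log(phi) = %.4g + %.4g * x + s, var(s) = %.4g\n",
                f$delta0, f$delta1, f$gamma_disp))
    cat(sprintf("log-likelihood = %.3f (%s)\n", f$logLik,
                if (f$converged) "converged" else "NOT converged"))
    if (length(f$boundary)) cat("boundary estimate(s):",
                                paste(f$boundary, collapse = ", "), "\n")
  }
  if (is.null(f$groups)) {
    cat("Allometric form: ", format_mi_formula(allometric_form(f)), "\n")
  }
  invisible(x)
}

#' Scatter plot of the fitted allometric relationship
#'
#' Plots litter weaning mass against adult mass on the log10-log10 scale with
#' the fitted marginal line (evaluated at the mean log10 duration for the
#' two-predictor methods).
#'
#' @param x An [allometry()] fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.allomfit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$x, d$y,
                 xlab = expression(log[10] ~ "adult mass [g]"),
                 ylab = expression(log[10] ~ "litter weaning mass [g]"),
                 pch = 16, col = grDevices::grey(0.2, 0.5), ...)
  xs <- seq(min(d$x), max(d$x), length.out = 50)
  nd <- data.frame(x = xs)
  if (x$method %in% c("mslr", "mplmm")) nd$z <- mean(d$z)
  if (!is.null(x$groups)) nd[[x$groups]] <- levels(d[[x$groups]])[1]
  graphics::lines(xs, predict(x, nd), col = "firebrick", lwd = 2)
  invisible(x)
}
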