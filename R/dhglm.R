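# Heteroscedastic phylogenetic linear mixed model (double hierarchical model).
#
# Mean model:        y = X beta + r + eps,  r ~ N(0, lambda * rho(Lambda))
# Dispersion model:  eps_i ~ N(0, phi_i),   log(phi_i) = delta0 + delta1 * x_i + s_i
#                    s_i ~ N(0, gamma), independent across species
#
# rho(Lambda) = Lambda * rho + (1 - Lambda) * I is the Pagel-scaled
# Brownian-motion correlation of the tree. All analysis variables are log10;
# the dispersion linear predictor is on the natural-log variance scale.
#
# Fitting follows the standard alternating (h-likelihood style) scheme for
# double hierarchical models:
#   (i)  mean model: given the per-species variances phi, the phylogenetic
#        random effect is integrated out exactly and (beta, lambda) are
#        estimated by maximising the Gaussian marginal likelihood (lambda by
#        a one-dimensional search, beta by GLS);
#   (ii) dispersion model: squared conditional residuals, standardised by
#        their leverages so their conditional mean is phi, are treated as
#        Gamma responses (phi * chi-squared_1 is Gamma with shape 1/2);
#        (delta0, delta1, gamma) are estimated by maximising the exact
#        marginal likelihood of this Gamma mixture (the scalar random effect
#        integrates by Gauss-Hermite quadrature), and s by its conditional
#        mode.
# The two steps iterate to joint convergence (relative change < 1e-6,
# at most 200 sweeps). Pagel's Lambda is profiled by an outer
# one-dimensional optimisation of the reported marginal log-likelihood,
# which is computed at the estimates with the dispersion random effect
# handled by a Laplace approximation (exactly, when gamma = 0).
# The leverage standardisation in (ii) is what keeps the dispersion model
# from chasing individual residuals (the well-known instability of naive
# joint maximisation over per-observation variances).

#' Optimiser settings for the mixed-model fits
#'
#' @param outer_maxit Maximum Nelder-Mead iterations for the variance
#'   parameters at fixed Pagel Lambda.
#' @param outer_reltol Relative convergence tolerance of that search.
#' @param profile_tol Absolute tolerance on Lambda in the outer
#'   one-dimensional profile optimisation.
#' @param inner_maxit,inner_tol Newton iteration cap and objective tolerance
#'   for the dispersion random-effect mode.
#' @param jitter Ridge added to covariance diagonals before factorisation.
#' @return A list of settings for [allometry()] with the mixed methods.
#' @export
dhglm_control <- function(outer_maxit = 500L, outer_reltol = 1e-8,
                          profile_tol = 0.01,
                          inner_maxit = 50L, inner_tol = 1e-9,
                          jitter = 1e-10) {
  list(outer_maxit = outer_maxit, outer_reltol = outer_reltol,
       profile_tol = profile_tol, inner_maxit = inner_maxit,
       inner_tol = inner_tol, jitter = jitter)
}

# Cholesky log-density of N(0, V); returns list(ll, ch) or NULL on failure.
chol_mvn <- function(e, V, jitter) {
  diag(V) <- diag(V) + jitter
  ch <- tryCatch(chol(V), error = function(cnd) NULL)
  if (is.null(ch)) return(NULL)
  u <- backsolve(ch, e, transpose = TRUE)
  list(ll = -0.5 * (length(e) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(u^2)),
       ch = ch)
}

# GLS fixed effects given a Cholesky factor of V.
gls_beta <- function(ch, X, y) {
  Xs <- backsolve(ch, X, transpose = TRUE)
  ys <- backsolve(ch, y, transpose = TRUE)
  qr.coef(qr(Xs), ys)
}

# Negative Hessian of the s-objective given V^{-1}, q = V^{-1} e and phi.
neg_hessian_s <- function(Vi, q, phi, gamma) {
  PV <- phi * Vi                         # rows scaled: PV[i, j] = phi_i * Vi[i, j]
  Hn <- -(0.5 * PV * t(PV) - (phi * q) %*% t(phi * q) * Vi)
  diag(Hn) <- diag(Hn) + 0.5 * phi * diag(Vi) - 0.5 * phi * q^2 + 1 / gamma
  Hn
}

# Laplace objective over s at fixed (beta, variance params):
# f(s) = log N(y - X beta; 0, lambda*rhoL + diag(exp(eta + s))) + log N(s; 0, gamma I)
# Returns the mode, the marginal ll with Laplace correction, and diagnostics.
laplace_s <- function(e, eta, gamma, A, s0, control) {
  n <- length(e)
  s <- as.numeric(s0)
  f_of <- function(s) {
    phi <- exp(eta + s)
    V <- A
    diag(V) <- diag(V) + phi
    d <- chol_mvn(e, V, control$jitter)
    if (is.null(d)) return(NULL)
    list(f = d$ll - 0.5 * (n * log(2 * pi * gamma) + sum(s^2) / gamma),
         ch = d$ch, phi = phi)
  }
  cur <- f_of(s)
  if (is.null(cur)) { s <- rep(0, n); cur <- f_of(s) }
  if (is.null(cur)) return(NULL)
  for (it in seq_len(control$inner_maxit)) {
    Vi <- chol2inv(cur$ch)
    q <- as.numeric(Vi %*% e)
    phi <- cur$phi
    grad <- -0.5 * phi * diag(Vi) + 0.5 * phi * q^2 - s / gamma
    Hn <- neg_hessian_s(Vi, q, phi, gamma)
    step <- newton_step(Hn, grad)
    if (is.null(step)) return(NULL)
    ls <- line_search(f_of, cur, s, step)
    s <- ls$s; improved <- ls$cur$f - cur$f; cur <- ls$cur
    if (abs(improved) < control$inner_tol && max(abs(grad)) < 1e-5) break
  }
  # Laplace correction with the exact Hessian at the mode
  Vi <- chol2inv(cur$ch)
  q <- as.numeric(Vi %*% e)
  Hn <- neg_hessian_s(Vi, q, cur$phi, gamma)
  chH <- tryCatch(chol(Hn + diag(control$jitter, n)), error = function(cnd) NULL)
  if (is.null(chH)) return(NULL)
  ll <- cur$f + 0.5 * n * log(2 * pi) - sum(log(diag(chH)))
  list(ll = ll, s = s, ch = cur$ch, phi = cur$phi)
}

newton_step <- function(Hn, grad) {
  tau <- 0
  n <- length(grad)
  repeat {                               # damped Newton: ensure -H + tau I is PD
    chH <- tryCatch(chol(Hn + diag(tau, n)), error = function(cnd) NULL)
    if (!is.null(chH))
      return(as.numeric(backsolve(chH, backsolve(chH, grad, transpose = TRUE))))
    tau <- if (tau == 0) 1e-4 * max(abs(diag(Hn)), 1) else tau * 10
    if (tau > 1e8) return(NULL)
  }
}

line_search <- function(f_of, cur, s, step) {
  alpha <- 1
  repeat {                               # backtracking line search on f
    nxt <- f_of(s + alpha * step)
    if (!is.null(nxt) && nxt$f >= cur$f - 1e-12)
      return(list(s = s + alpha * step, cur = nxt))
    alpha <- alpha / 2
    if (alpha < 1e-8) return(list(s = s, cur = cur))
  }
}

# Gauss-Hermite nodes and weights (Golub-Welsch), for integrating the
# dispersion random effect: int f(s) N(s; 0, g) ds
#   = sum_k (w_k / sqrt(pi)) f(sqrt(2 g) t_k).
gauss_hermite <- function(K) {
  off <- sqrt(seq_len(K - 1) / 2)
  J <- diag(0, K)
  J[cbind(seq_len(K - 1), seq_len(K - 1) + 1L)] <- off
  J[cbind(seq_len(K - 1) + 1L, seq_len(K - 1))] <- off
  ed <- eigen(J, symmetric = TRUE)
  ord <- order(ed$values)
  list(t = ed$values[ord], w = (ed$vectors[1, ord]^2))   # weights sum to 1
}

# Marginal log-likelihood of the Gamma(1/2) dispersion mixture:
# d_i | s ~ Gamma(shape 1/2, scale 2 exp(eta_i + s)), s ~ N(0, gamma).
# The Gamma(1/2, 2 mu) log-density is
#   -0.5 log d - lgamma(1/2) - 0.5 log(2 mu) - d / (2 mu),
# written out so the quadrature grid evaluates as one outer product.
disp_marginal_ll <- function(par, d, xd, gh) {
  eta <- par[1] + par[2] * xd
  gamma <- exp(par[3])
  sk <- sqrt(2 * gamma) * gh$t
  u <- d * exp(-eta)
  const_i <- -0.5 * log(d) - lgamma(0.5) - 0.5 * log(2) - 0.5 * eta
  colk <- log(gh$w) - 0.5 * sk
  lmat <- (-0.5 * outer(u, exp(-sk))) + rep(colk, each = length(d))
  m <- lmat[cbind(seq_along(d), max.col(lmat, ties.method = "first"))]
  sum(const_i + m + log(rowSums(exp(lmat - m))))
}

# Conditional mode of s_i given d_i (concave scalar problems, vectorised).
disp_ranef_mode <- function(d, eta, gamma) {
  if (gamma < 1e-10) return(numeric(length(d)))
  s <- numeric(length(d))
  for (it in 1:40) {
    u <- d * exp(-(eta + s)) / 2
    g <- -0.5 + u - s / gamma
    h <- -u - 1 / gamma
    step <- -g / h
    step <- pmin(pmax(step, -2), 2)      # trust region; objective is concave
    s <- s + step
    if (max(abs(g)) < 1e-10) break
  }
  s
}

# Mean-model step at fixed phi: profile the Gaussian marginal likelihood
# over beta (GLS) and lambda (Brent on log lambda). After the first sweep
# the search is restricted to a window around the previous optimum (with a
# widening fallback), which keeps the per-sweep Cholesky count small.
mean_step <- function(eng, rhoL, phi, warm = NULL, fixed = NULL) {
  obj <- function(loglam) {
    V <- exp(loglam) * rhoL
    diag(V) <- diag(V) + phi + eng$control$jitter
    ch <- tryCatch(chol(V), error = function(cnd) NULL)
    if (is.null(ch)) return(1e10)
    beta <- gls_beta(ch, eng$X, eng$y)
    if (anyNA(beta)) return(1e10)
    e <- eng$y - as.numeric(eng$X %*% beta)
    u <- backsolve(ch, e, transpose = TRUE)
    0.5 * (eng$n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(u^2))
  }
  if (!is.null(fixed)) {
    op <- list(minimum = fixed, objective = obj(fixed))
  } else if (is.null(warm)) {
    op <- stats::optimize(obj, c(-25, 8), tol = 1e-4)
  } else {
    lo <- max(warm - 1.5, -25); hi <- min(warm + 1.5, 8)
    op <- stats::optimize(obj, c(lo, hi), tol = 1e-4)
    if (op$minimum < lo + 0.05 || op$minimum > hi - 0.05) {
      op <- stats::optimize(obj, c(-25, 8), tol = 1e-4)   # window missed: widen
    }
  }
  lambda <- exp(op$minimum)
  V <- lambda * rhoL
  diag(V) <- diag(V) + phi + eng$control$jitter
  ch <- chol(V)
  beta <- gls_beta(ch, eng$X, eng$y)
  e <- eng$y - as.numeric(eng$X %*% beta)
  Vi <- chol2inv(ch)
  ViX <- Vi %*% eng$X
  XtViX_inv <- chol2inv(chol(crossprod(eng$X, ViX)))
  P_diag <- diag(Vi) - rowSums((ViX %*% XtViX_inv) * ViX)
  list(lambda = lambda, beta = beta, e = e, ch = ch, Vi = Vi,
       P_diag = P_diag, ll = -op$objective, vcov_beta = XtViX_inv)
}

new_dhglm_engine <- function(data, tree, X, control) {
  eng <- new.env(parent = emptyenv())
  eng$y <- data$y
  eng$X <- X
  eng$xd <- data$x                        # dispersion covariate: log10 adult mass
  eng$n <- nrow(data)
  corr <- bm_correlation(tree, data$species)
  eng$rho <- corr$rho
  eng$control <- control
  eng$gh <- gauss_hermite(25L)
  ols <- stats::lm.fit(X, data$y)
  e0 <- ols$residuals
  eng$beta_init <- ols$coefficients
  # initialisation: delta0 = log mean squared OLS residual, delta1 = 0,
  # gamma = 0.01; the dispersion fit warm-starts from here
  eng$disp_init <- c(log(mean(e0^2)), 0, log(0.01))
  eng
}

# Alternating fit at fixed Pagel Lambda. Returns all parameter estimates and
# the Laplace marginal log-likelihood used for profiling and LRTs.
dhglm_inner_fit <- function(eng, Lambda) {
  ctrl <- eng$control
  n <- eng$n
  rhoL <- Lambda * eng$rho
  diag(rhoL) <- 1
  disp_par <- eng$disp_par %||% eng$disp_init
  s <- eng$shat %||% numeric(n)
  if (length(s) != n) s <- numeric(n)
  prev <- -Inf
  converged <- FALSE
  ms <- NULL
  loglam_warm <- eng$loglam_warm
  for (it in seq_len(200L)) {
    phi <- exp(disp_par[1] + disp_par[2] * eng$xd + s)
    # re-profile lambda on a schedule; between re-profiles the mean step
    # reuses the current value (one factorisation instead of a line search)
    ms <- mean_step(eng, rhoL, phi, warm = loglam_warm,
                    fixed = if (!is.null(loglam_warm) && it %% 3 != 1) loglam_warm)
    loglam_warm <- log(ms$lambda)
    # leverage-standardised squared conditional residuals, conditional mean phi
    ehat <- phi * as.numeric(ms$Vi %*% ms$e)
    lev <- pmax(phi * ms$P_diag, 1e-10)
    d <- pmax(ehat^2 / lev, 1e-12)
    # log gamma capped at 3 (variance 20 on the log-variance scale is far
    # beyond anything biological, and the quadrature degrades beyond it)
    disp_obj <- function(p) {
      if (!all(is.finite(p)) || p[3] > 3 || max(abs(p[1:2])) > 50) return(1e10)
      val <- disp_marginal_ll(p, d, eng$xd, eng$gh)
      if (is.finite(val)) -val else 1e10
    }
    if (disp_obj(disp_par) >= 1e10) disp_par <- eng$disp_init
    dop <- stats::optim(disp_par, disp_obj, method = "Nelder-Mead",
                        control = list(maxit = 200, reltol = 1e-8))
    disp_par <- dop$par
    s <- disp_ranef_mode(d, disp_par[1] + disp_par[2] * eng$xd, exp(disp_par[3]))
    if (it %% 3 == 1) {                  # compare successive sweeps that
      crit <- ms$ll + (-dop$value)       # re-profiled lambda
      if (is.finite(prev) && abs(crit - prev) < 1e-6 * (abs(prev) + 1)) {
        converged <- TRUE
        break
      }
      prev <- crit
    }
  }
  eng$disp_par <- disp_par
  eng$shat <- s
  eng$loglam_warm <- loglam_warm
  gamma <- exp(disp_par[3])
  phi <- exp(disp_par[1] + disp_par[2] * eng$xd + s)
  A <- ms$lambda * rhoL
  # reported likelihood: marginal over both random effects at the estimates.
  # Below 1e-6 the dispersion random effect is scientifically negligible and
  # the Laplace pass is ill-conditioned, so the exact gamma = 0 form is used.
  if (gamma < 1e-6) {
    V <- A
    diag(V) <- diag(V) + exp(disp_par[1] + disp_par[2] * eng$xd)
    dd <- chol_mvn(ms$e, V, ctrl$jitter)
    ll <- if (is.null(dd)) -1e10 else dd$ll
  } else {
    lap <- laplace_s(ms$e, disp_par[1] + disp_par[2] * eng$xd, gamma, A, s, ctrl)
    ll <- if (is.null(lap)) -1e10 else lap$ll
  }
  list(ll = ll, lambda = ms$lambda, beta = ms$beta,
       delta0 = disp_par[1], delta1 = disp_par[2], gamma = gamma,
       s = s, phi = phi, e = ms$e, ch_V = ms$ch, A = A,
       vcov_beta = ms$vcov_beta, convergence = if (converged) 0L else 1L)
}

fit_dhglm <- function(data, tree, duration, level, groups = NULL,
                      interactions = NULL, lambda_pagel = NULL,
                      control = dhglm_control()) {
  if (is.null(tree))
    stop_allomi("mixed-model methods require a phylogenetic tree", "allomi_validation_error")
  n <- nrow(data)
  if (n < 10L)
    stop_allomi("mixed-model fits need at least 10 species", "allomi_validation_error")
  fml <- ols_formula(duration, groups, interactions)
  X <- stats::model.matrix(fml, data)
  eng <- new_dhglm_engine(data, tree, X, control)

  offdiag_max <- max(abs(eng$rho[upper.tri(eng$rho)]))
  lambda_unident <- FALSE
  profile <- NULL
  if (offdiag_max < 1e-10) {              # star phylogeny: likelihood flat in Lambda
    lambda_unident <- TRUE
    Lambda_hat <- 0
    inner <- dhglm_inner_fit(eng, Lambda_hat)
  } else if (!is.null(lambda_pagel)) {
    if (lambda_pagel < 0 || lambda_pagel > 1)
      stop_allomi("Pagel's Lambda must lie in [0, 1]", "allomi_domain_error")
    Lambda_hat <- lambda_pagel
    inner <- dhglm_inner_fit(eng, Lambda_hat)
  } else {
    trace <- list()
    prof_obj <- function(L) {
      res <- dhglm_inner_fit(eng, L)
      trace[[length(trace) + 1L]] <<- c(Lambda = L, ll = res$ll)
      res$ll
    }
    op <- stats::optimise(prof_obj, c(0, 1), maximum = TRUE,
                          tol = control$profile_tol)
    profile <- do.call(rbind, trace)
    if (diff(range(profile[, "ll"])) < 1e-6) lambda_unident <- TRUE
    Lambda_hat <- op$maximum
    inner <- dhglm_inner_fit(eng, Lambda_hat)
  }

  lambda <- inner$lambda
  delta0 <- inner$delta0; delta1 <- inner$delta1; gamma <- inner$gamma
  ll <- inner$ll
  beta <- inner$beta
  names(beta) <- colnames(X)
  fitted_marg <- as.numeric(X %*% beta)
  resid <- data$y - fitted_marg

  # BLUP of the phylogenetic random effect at the fitted parameters
  Vi_e <- backsolve(inner$ch_V, backsolve(inner$ch_V, inner$e, transpose = TRUE))
  r_hat <- as.numeric(inner$A %*% Vi_e)
  # approximate (Wald) intervals for the fixed effects from the GLS vcov
  vcov_beta <- inner$vcov_beta
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vcov_beta))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(beta - zq * se, beta + zq * se)
  dimnames(ci) <- list(colnames(X),
                       paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2)), "%"))

  if (inner$convergence != 0)
    warning("mixed-model fit did not reach joint convergence within 200 sweeps; ",
            "estimates returned with converged = FALSE")
  boundary <- character()
  if (lambda < 1e-6) boundary <- c(boundary, "lambda")
  if (gamma < 1e-6) boundary <- c(boundary, "gamma")
  if (!lambda_unident && is.null(lambda_pagel) &&
      (Lambda_hat < 0.005 || Lambda_hat > 0.995))
    boundary <- c(boundary, "Lambda")

  list(coefficients = beta,
       n = n,
       r_squared = stats::cor(data$y, fitted_marg)^2,
       sigma = sqrt(mean(resid^2)),
       ci = ci, vcov = vcov_beta,
       fitted_marginal = fitted_marg,
       residuals = resid,
       lambda_phy = lambda, Lambda = Lambda_hat,
       delta0 = delta0, delta1 = delta1, gamma_disp = gamma,
       phi = as.numeric(eng$phi),
       ranef_phylo = r_hat, ranef_disp = as.numeric(eng$s),
       logLik = ll,
       converged = inner$convergence == 0,
       lambda_unidentifiable = lambda_unident,
       boundary = boundary,
       profile = profile,
       tree = tree,
       control = control,
       lambda_fixed = lambda_pagel,
       groups = groups, interactions = if (!is.null(groups)) interactions,
       formula = fml)
}

#' Marginal log-likelihood of the heteroscedastic phylogenetic model
#'
#' Evaluates the marginal log-likelihood of the double hierarchical model at
#' the supplied parameter values: the phylogenetic random effect is
#' integrated out exactly (it is Gaussian) and the dispersion random effect
#' `s` by a Laplace approximation around its conditional mode. With
#' `gamma = 0` the result is the exact Gaussian log-likelihood with
#' covariance `lambda * rho(Lambda) + diag(exp(delta0 + delta1 * x))`, which
#' is also exactly computable by a direct matrix oracle. Deterministic for
#' fixed inputs.
#'
#' @param params Named list or vector with `beta` (fixed effects, in the
#'   order of the model matrix), `lambda`, `delta0`, `delta1`, `gamma`.
#' @param data Data frame with `species`, `y`, `x` (and `z` if `duration`).
#' @param tree Phylogeny covering the species (or a [bm_correlation()]).
#' @param Lambda Fixed Pagel scaling in `[0, 1]`.
#' @param duration Include `z` in the mean model?
#' @param control See [dhglm_control()].
#' @return The log-likelihood (scalar).
#' @export
dhglm_loglik <- function(params, data, tree, Lambda, duration = FALSE,
                         control = dhglm_control()) {
  if (any(c(params$lambda, params$gamma) < 0))
    stop_allomi("variance parameters must be non-negative", "allomi_domain_error")
  X <- stats::model.matrix(ols_formula(duration, NULL, NULL), data)
  corr <- if (inherits(tree, "bm_correlation")) tree else bm_correlation(tree, data$species)
  rhoL <- pagel_scale(corr, Lambda)$rho
  A <- params$lambda * rhoL
  eta <- params$delta0 + params$delta1 * data$x
  e <- data$y - as.numeric(X %*% params$beta)
  n <- nrow(data)
  if (params$gamma < 1e-10) {
    V <- A
    diag(V) <- diag(V) + exp(eta)
    d <- chol_mvn(e, V, control$jitter)
    if (is.null(d))
      stop_allomi("covariance matrix not positive definite", "allomi_numeric_error")
    return(d$ll)
  }
  lap <- laplace_s(e, eta, params$gamma, A, rep(0, n), control)
  if (is.null(lap))
    stop_allomi("covariance matrix not positive definite", "allomi_numeric_error")
  lap$ll
}

#' Profile Pagel's Lambda
#'
#' Profile log-likelihood of the Pagel scaling parameter: at each candidate
#' Lambda all other parameters (fixed effects, `lambda`, `delta0`, `delta1`,
#' `gamma`) are re-maximised. The estimate is the argmax over `[0, 1]`; the
#' optional confidence interval is the set where the profile drops by less
#' than `qchisq(level, 1) / 2`.
#'
#' @inheritParams allometry
#' @param duration Include the duration predictor (MPLMM) or not (PLMM).
#' @param grid Optional vector of Lambda values to evaluate in addition to
#'   the one-dimensional optimisation.
#' @param ci Compute the profile confidence interval?
#' @param level Confidence level for the profile interval.
#' @return List with `Lambda`, `logLik`, `profile` (matrix of evaluated
#'   points), `ci` (or `NULL`), and `unidentifiable` (flat-profile flag).
#' @export
profile_pagel <- function(data, tree, duration = FALSE, grid = NULL,
                          ci = FALSE, level = 0.95,
                          control = dhglm_control()) {
  data <- as.data.frame(data)
  req <- c("species", "y", "x", if (duration) "z")
  data <- data[stats::complete.cases(data[, req, drop = FALSE]), , drop = FALSE]
  X <- stats::model.matrix(ols_formula(duration, NULL, NULL), data)
  eng <- new_dhglm_engine(data, tree, X, control)
  evals <- list()
  f <- function(L) {
    res <- dhglm_inner_fit(eng, L)
    evals[[length(evals) + 1L]] <<- c(Lambda = L, ll = res$ll)
    res$ll
  }
  op <- stats::optimise(f, c(0, 1), maximum = TRUE, tol = control$profile_tol)
  for (L in grid %||% numeric()) f(L)
  prof <- do.call(rbind, evals)
  prof <- prof[order(prof[, "Lambda"]), , drop = FALSE]
  unident <- diff(range(prof[, "ll"])) < 1e-6
  out <- list(Lambda = op$maximum, logLik = op$objective, profile = prof,
              ci = NULL, unidentifiable = unident)
  if (ci && !unident) {
    drop <- stats::qchisq(level, 1) / 2
    thr <- op$objective - drop
    g <- function(L) f(L) - thr
    lo <- if (g(0) >= 0) 0 else stats::uniroot(g, c(0, op$maximum), tol = 1e-3)$root
    hi <- if (g(1) >= 0) 1 else stats::uniroot(g, c(op$maximum, 1), tol = 1e-3)$root
    out$ci <- c(lo, hi)
  }
  out
}

#' @export
logLik.allomfit_dhglm <- function(object, ...) {
  # variance parameters lambda, delta0, delta1, gamma counted; the profiled
  # Pagel Lambda is not (so PLMM-vs-SLR has 3 nominal df)
  structure(object$logLik, df = length(object$coefficients) + 4L,
            nobs = object$n, class = "logLik")
}

#' @rdname predict.allomfit
#' @export
predict.allomfit_dhglm <- function(object, newdata = NULL,
                                   type = c("marginal", "conditional"),
                                   scale = c("log10", "response"), ...) {
  type <- match.arg(type)
  scale <- match.arg(scale)
  if (type == "marginal") {
    yhat <- if (is.null(newdata)) object$fitted_marginal
            else marginal_linear_predictor(object, newdata)
  } else {
    if (is.null(newdata)) {
      yhat <- object$fitted_marginal + object$ranef_phylo
    } else {
      if (!"species" %in% names(newdata))
        stop_allomi("conditional predictions need a `species` column", "allomi_validation_error")
      i <- match(normalize_species(newdata$species),
                 normalize_species(object$data$species))
      if (anyNA(i))
        stop_allomi(paste0("species not in the training data: ",
                           paste(newdata$species[is.na(i)], collapse = ", ")),
                    "allomi_validation_error")
      yhat <- marginal_linear_predictor(object, newdata) + object$ranef_phylo[i]
    }
  }
  if (scale == "response") 10^yhat else yhat
}

#' @export
simulate.allomfit_dhglm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  corr <- bm_correlation(object$tree, object$data$species)
  rhoL <- pagel_scale(corr, object$Lambda)$rho
  S <- object$lambda_phy * rhoL
  diag(S) <- diag(S) + object$control$jitter
  L <- t(chol(S))
  mu <- object$fitted_marginal
  eta <- object$delta0 + object$delta1 * object$data$x
  out <- matrix(NA_real_, n, nsim)
  for (k in seq_len(nsim)) {
    r <- as.numeric(L %*% stats::rnorm(n))
    s <- stats::rnorm(n, 0, sqrt(object$gamma_disp))
    out[, k] <- mu + r + stats::rnorm(n, 0, sqrt(exp(eta + s)))
  }
  out
}
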