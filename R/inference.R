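# Nonparametric tests and parametric-bootstrap inference.
#
# kruskal.test, quade.test and cor.test are wrapped from stats. The
# Wilcoxon-Mann-Whitney and Wilcoxon-Pratt signed-rank tests are implemented
# here because the package needs (a) tie-corrected asymptotic z statistics
# and (b) exact enumeration with Pratt's zero handling; exact null
# distributions are built by shifted-convolution dynamic programming over
# doubled midranks, so ties cost nothing.

#' Pearson correlation test
#'
#' @param x,y Numeric vectors of equal length (n >= 3), finite variance.
#' @return An `"htest"` from [stats::cor.test()] (statistic `t`, estimate
#'   `r`).
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop_allomi("need at least 3 paired observations", "allomi_validation_error")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop_allomi("zero variance: correlation undefined", "allomi_validation_error")
  stats::cor.test(x, y)
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' Midrank tie correction, chi-squared reference with `groups - 1` df
#' (delegates to [stats::kruskal.test()]).
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @return An `"htest"`.
#' @export
kruskal_wallis <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2L)
    stop_allomi("need at least two groups", "allomi_validation_error")
  if (any(table(g) == 0L))
    stop_allomi("every group must be nonempty", "allomi_validation_error")
  if (length(unique(values)) == 1L) {    # all tied: H = 0 by convention
    return(structure(list(statistic = c("Kruskal-Wallis chi-squared" = 0),
                          parameter = c(df = nlevels(g) - 1L), p.value = 1,
                          method = "Kruskal-Wallis rank sum test",
                          data.name = "values by groups"),
                     class = "htest"))
  }
  stats::kruskal.test(values, g)
}

#' Quade test for blocked comparisons of several methods
#'
#' Species are blocks and MI-producing methods are treatments; the test asks
#' whether the methods produce systematically different values. Delegates to
#' [stats::quade.test()]; df are `k - 1` and `(k - 1)(b - 1)`.
#'
#' @param mat Numeric matrix, blocks (species) in rows, treatments (methods)
#'   in columns.
#' @return An `"htest"` with the Quade `F` statistic.
#' @export
quade_compare <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L || nrow(mat) < 2L)
    stop_allomi("need at least 2 treatments and 2 blocks", "allomi_validation_error")
  rng <- apply(mat, 1, function(r) diff(range(r)))
  if (all(rng == 0))
    stop_allomi("all blocks are constant: Quade statistic undefined",
                "allomi_validation_error")
  stats::quade.test(mat)
}

# Exact distribution of a sum of a fixed-size subset of scores, by dynamic
# programming. Scores must be non-negative integers (doubled midranks).
# Returns counts over sums 0..sum(scores) for each subset size 0..m.
subset_sum_counts <- function(scores, m) {
  total <- sum(scores)
  f <- matrix(0, nrow = m + 1L, ncol = total + 1L)   # [size + 1, sum + 1]
  f[1, 1] <- 1
  for (sc in scores) {
    for (k in seq(min(m, 1e9), 1L)) {
      nz <- which(f[k, ] > 0)
      if (length(nz)) f[k + 1L, nz + sc] <- f[k + 1L, nz + sc] + f[k, nz]
    }
  }
  f
}

#' Wilcoxon-Mann-Whitney test for two independent groups
#'
#' Asymptotic tie-corrected standardised `z` statistic (no continuity
#' correction), or the exact permutation null enumerated over all
#' `choose(n1 + n2, n1)` group assignments when the combined sample size is
#' within `exact_cap`. Swapping the two groups flips the sign of `z`.
#'
#' @param g1,g2 Numeric vectors (both nonempty).
#' @param mode `"auto"` (exact when `n1 + n2 <= exact_cap`), `"exact"`, or
#'   `"asymptotic"`.
#' @param alternative `"two.sided"`, `"less"`, or `"greater"` (`g1` vs `g2`).
#' @param exact_cap Combined-size cap for exact enumeration.
#' @return An `"htest"` with statistic `z` (asymptotic, also reported for
#'   reference in exact mode), the rank-sum `W`, `p.value`, and an `exact`
#'   flag.
#' @export
mann_whitney <- function(g1, g2, mode = c("auto", "exact", "asymptotic"),
                         alternative = c("two.sided", "less", "greater"),
                         exact_cap = 20L) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  if (!length(g1) || !length(g2))
    stop_allomi("both groups must be nonempty", "allomi_validation_error")
  n1 <- length(g1); n2 <- length(g2); N <- n1 + n2
  rk <- rank(c(g1, g2))
  W <- sum(rk[seq_len(n1)])
  EW <- n1 * (N + 1) / 2
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  VW <- n1 * n2 / 12 * ((N + 1) - tie_term)
  z <- if (VW > 0) (W - EW) / sqrt(VW) else 0
  do_exact <- mode == "exact" || (mode == "auto" && N <= exact_cap)
  if (do_exact) {
    scores <- as.integer(round(2 * rk))
    f <- subset_sum_counts(scores, n1)
    counts <- f[n1 + 1L, ]
    sums <- (seq_along(counts) - 1L) / 2            # undo the doubling
    tot <- sum(counts)
    p <- switch(alternative,
      less      = sum(counts[sums <= W + 1e-9]) / tot,
      greater   = sum(counts[sums >= W - 1e-9]) / tot,
      two.sided = min(1, sum(counts[abs(sums - EW) >= abs(W - EW) - 1e-9]) / tot))
  } else {
    p <- switch(alternative,
      less      = stats::pnorm(z),
      greater   = stats::pnorm(z, lower.tail = FALSE),
      two.sided = 2 * stats::pnorm(-abs(z)))
  }
  structure(list(statistic = c(z = z), parameter = NULL,
                 p.value = p, estimate = c(W = W),
                 alternative = alternative,
                 method = paste0(if (do_exact) "Exact " else "Asymptotic (tie-corrected) ",
                                 "Wilcoxon-Mann-Whitney test"),
                 data.name = "g1 vs g2", exact = do_exact),
            class = "htest")
}

#' Wilcoxon signed-rank test with Pratt's zero handling
#'
#' Differences of zero are ranked together with the rest (so they influence
#' the ranks of the nonzero differences) and then discarded from the
#' statistic — Pratt's treatment. The exact two-sided p doubles the smaller
#' tail of the null enumerated over all sign assignments of the nonzero
#' ranks; the asymptotic version uses the zero- and tie-corrected normal
#' approximation.
#'
#' @param differences Numeric vector of paired differences.
#' @param mode `"auto"` (exact when the number of nonzero differences is at
#'   most `exact_cap`), `"exact"`, or `"asymptotic"`.
#' @param exact_cap Cap on nonzero differences for exact mode.
#' @return An `"htest"` with statistic `z`, the positive-rank sum `V`,
#'   `p.value` (two-sided), `exact` and `degenerate` flags.
#' @export
signed_rank_pratt <- function(differences,
                              mode = c("auto", "exact", "asymptotic"),
                              exact_cap = 25L) {
  mode <- match.arg(mode)
  d <- differences[!is.na(differences)]
  n <- length(d)
  if (!n) stop_allomi("no differences supplied", "allomi_validation_error")
  if (all(d == 0)) {
    return(structure(list(statistic = c(z = 0), p.value = 1,
                          estimate = c(V = 0),
                          method = "Wilcoxon-Pratt signed-rank test (degenerate: all zeros)",
                          alternative = "two.sided", data.name = "differences",
                          exact = FALSE, degenerate = TRUE),
                     class = "htest"))
  }
  rk <- rank(abs(d))                     # zeros ranked, then dropped (Pratt)
  nz <- d != 0
  V <- sum(rk[nz & d > 0])
  n0 <- sum(!nz)
  # zero- and tie-corrected moments (Pratt 1959)
  EV <- (n * (n + 1) / 2 - n0 * (n0 + 1) / 2) / 2
  ties <- table(rk[nz])
  VV <- (n * (n + 1) * (2 * n + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
    sum(ties^3 - ties) / 48
  z <- if (VV > 0) (V - EV) / sqrt(VV) else 0
  m <- sum(nz)
  do_exact <- mode == "exact" || (mode == "auto" && m <= exact_cap)
  if (do_exact) {
    scores <- as.integer(round(2 * rk[nz]))
    f <- subset_sum_counts(scores, m)
    counts <- colSums(f)                 # any subset of signs may be positive
    sums <- (seq_along(counts) - 1L) / 2
    tot <- sum(counts)
    p_lo <- sum(counts[sums <= V + 1e-9]) / tot
    p_hi <- sum(counts[sums >= V - 1e-9]) / tot
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(statistic = c(z = z), p.value = p, estimate = c(V = V),
                 method = paste0(if (do_exact) "Exact " else "Asymptotic ",
                                 "Wilcoxon-Pratt signed-rank test"),
                 alternative = "two.sided", data.name = "differences",
                 exact = do_exact, degenerate = FALSE),
            class = "htest")
}

# Refit the same model specification on a new response vector.
refit_allomfit <- function(fit, y_new) {
  d <- fit$data
  d$y <- as.numeric(y_new)
  if (inherits(fit, "allomfit_dhglm")) {
    allometry(d, fit$method, tree = fit$tree, level = fit$level,
              groups = fit$groups, interactions = fit$interactions %||% c("mass", "duration"),
              lambda_pagel = fit$Lambda,   # Lambda held at the fitted value
              control = fit$control)
  } else {
    allometry(d, fit$method, level = fit$level, groups = fit$groups,
              interactions = fit$interactions %||% c("mass", "duration"))
  }
}

# Parameter vector reported in bootstrap summaries.
fit_param_vector <- function(fit) {
  out <- fit$coefficients
  if (inherits(fit, "allomfit_dhglm")) {
    c(out, lambda = fit$lambda_phy, delta0 = fit$delta0,
      delta1 = fit$delta1, gamma = fit$gamma_disp)
  } else {
    c(out, sigma = fit$sigma)
  }
}

#' Parametric-bootstrap confidence intervals
#'
#' Simulates `n_boot` response vectors from the fitted model, refits the same
#' specification on each, and returns percentile intervals for every
#' parameter. For the mixed models Pagel's Lambda is held at its fitted value
#' during the refits (its own interval comes from [profile_pagel()]).
#' Replicates whose refit fails are dropped and counted, never imputed.
#'
#' @param fit An [allometry()] fit.
#' @param n_boot Number of bootstrap replicates (>= 1).
#' @param seed Optional integer seed; the same seed reproduces the intervals
#'   exactly.
#' @param level Confidence level.
#' @param strict If more than 10% of refits fail: error when `TRUE`,
#'   warning otherwise.
#' @return Object of class `"mi_boot_ci"`: `estimates`, `ci` (matrix),
#'   `n_boot`, `n_failed`, `seed`, `level`.
#' @export
bootstrap_ci <- function(fit, n_boot = 1000L, seed = NULL, level = 0.95,
                         strict = FALSE) {
  if (n_boot < 1L) stop_allomi("n_boot must be at least 1", "allomi_validation_error")
  if (!is.null(seed)) set.seed(seed)
  sims <- simulate(fit, nsim = n_boot)
  est <- fit_param_vector(fit)
  draws <- matrix(NA_real_, n_boot, length(est),
                  dimnames = list(NULL, names(est)))
  for (k in seq_len(n_boot)) {
    rf <- tryCatch(suppressMessages(refit_allomfit(fit, sims[, k])),
                   error = function(cnd) NULL)
    if (!is.null(rf)) draws[k, ] <- fit_param_vector(rf)
  }
  ok <- stats::complete.cases(draws)
  n_failed <- sum(!ok)
  if (n_failed > 0.10 * n_boot) {
    msg <- sprintf("%d of %d bootstrap refits failed", n_failed, n_boot)
    if (strict) stop_allomi(msg, "allomi_convergence_error") else warning(msg)
  }
  alpha <- (1 - level) / 2
  ci <- t(apply(draws[ok, , drop = FALSE], 2, stats::quantile,
                probs = c(alpha, 1 - alpha), names = FALSE))
  colnames(ci) <- paste(format(100 * c(alpha, 1 - alpha)), "%")
  structure(list(estimates = est, ci = ci, n_boot = n_boot,
                 n_failed = n_failed, seed = seed, level = level),
            class = "mi_boot_ci")
}

#' @export
print.mi_boot_ci <- function(x, ...) {
  cat(sprintf("Parametric bootstrap, %d replicates (%d failed), %g%% percentile CIs:\n",
              x$n_boot, x$n_failed, 100 * x$level))
  print(round(cbind(estimate = x$estimates, x$ci), 4))
  invisible(x)
}

#' Parametric-bootstrap likelihood-ratio test
#'
#' Tests a nested pair of fits on the same data. The observed statistic is
#' `2 * (logLik(alt) - logLik(null))`; its null distribution is estimated by
#' simulating responses from the null fit and refitting both models on each
#' draw. The p-value uses the `(1 + #{draws >= observed}) / (n + 1)`
#' convention, so it is never exactly zero. The nominal df counts fixed
#' effects plus variance parameters (Pagel's Lambda, being profiled,
#' is not counted).
#'
#' @param null_fit,alt_fit Nested [allometry()] fits of the same response
#'   (SMA/MA fits are not likelihood-based and are rejected).
#' @param n_boot Number of parametric-bootstrap draws.
#' @param seed Optional integer seed.
#' @return Object of class `"mi_boot_lrt"`: `statistic`, `df`, `p.value`,
#'   `p_chisq` (asymptotic reference), `null_draws`, `n_failed`, `seed`.
#' @export
bootstrap_lrt <- function(null_fit, alt_fit, n_boot = 1000L, seed = NULL) {
  if (n_boot < 1L) stop_allomi("n_boot must be at least 1", "allomi_validation_error")
  for (f in list(null_fit, alt_fit))
    if (f$method %in% c("sma", "ma"))
      stop_allomi("SMA/MA fits are not likelihood-based", "allomi_validation_error")
  if (null_fit$n != alt_fit$n ||
      !isTRUE(all.equal(null_fit$data$y, alt_fit$data$y)))
    stop_allomi("fits are not on the same response: not nested", "allomi_validation_error")
  ll0 <- as.numeric(logLik(null_fit)); df0 <- attr(logLik(null_fit), "df")
  ll1 <- as.numeric(logLik(alt_fit));  df1 <- attr(logLik(alt_fit), "df")
  if (df1 <= df0)
    stop_allomi("alternative model is not larger than the null: not nested",
                "allomi_validation_error")
  observed <- 2 * (ll1 - ll0)
  if (!is.null(seed)) set.seed(seed)
  sims <- simulate(null_fit, nsim = n_boot)
  draws <- rep(NA_real_, n_boot)
  for (k in seq_len(n_boot)) {
    stat <- tryCatch({
      f0 <- suppressMessages(refit_allomfit(null_fit, sims[, k]))
      f1 <- suppressMessages(refit_allomfit(alt_fit, sims[, k]))
      2 * (as.numeric(logLik(f1)) - as.numeric(logLik(f0)))
    }, error = function(cnd) NA_real_)
    draws[k] <- stat
  }
  ok <- !is.na(draws)
  p <- (1 + sum(draws[ok] >= observed)) / (sum(ok) + 1)
  structure(list(statistic = observed, df = df1 - df0, p.value = p,
                 p_chisq = stats::pchisq(observed, df1 - df0, lower.tail = FALSE),
                 null_draws = draws[ok], n_boot = n_boot,
                 n_failed = sum(!ok), seed = seed),
            class = "mi_boot_lrt")
}

#' @export
print.mi_boot_lrt <- function(x, ...) {
  cat(sprintf("Parametric-bootstrap LRT: LRT = %.3f, nominal df = %d\n",
              x$statistic, x$df))
  cat(sprintf("  bootstrap p = %.4g (%d draws, %d failed); chi-squared p = %.4g\n",
              x$p.value, x$n_boot, x$n_failed, x$p_chisq))
  invisible(x)
}
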