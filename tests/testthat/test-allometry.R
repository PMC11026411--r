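test_that("SLR recovers exact lines and degenerate cases error", {
  tab <- data.frame(species = c("a", "b", "c"), x = c(0, 1, 2), y = c(0, 1, 2))
  fit <- allometry(tab, "slr")
  expect_equal(unname(coef(fit)), c(0, 1), tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)

  tab$y <- c(3, 3, 3)
  fit0 <- allometry(tab, "slr")
  expect_equal(unname(coef(fit0)), c(3, 0), tolerance = 1e-12)

  tab$x <- c(1, 1, 1)
  expect_error(allometry(tab, "slr"), class = "allomi_degenerate_design")
})

test_that("MSLR recovers a noiseless plane exactly and rejects rank deficiency", {
  g <- expand.grid(x = 0:2, z = 0:2)
  tab <- data.frame(species = paste0("s", 1:9), x = g$x, z = g$z)
  tab$y <- 1 + 2 * tab$x - 0.5 * tab$z
  fit <- allometry(tab, "mslr")
  expect_equal(unname(coef(fit)), c(1, 2, -0.5), tolerance = 1e-12)

  tab$z <- 1
  expect_error(allometry(tab, "mslr"), class = "allomi_degenerate_design")
  tab$z <- tab$x * 2 + 3                 # perfectly collinear
  expect_error(allometry(tab, "mslr"), class = "allomi_degenerate_design")
})

test_that("SMA slope properties hold: exact line, |b| = sy/sx, b_sma = b_slr / r", {
  tab <- data.frame(species = c("a", "b", "c"), x = c(0, 1, 2), y = c(0, 2, 4))
  expect_equal(unname(coef(allometry(tab, "sma"))), c(0, 2), tolerance = 1e-12)

  for (seed in 1:5) {
    t2 <- make_line_table(n = 30, seed = seed, sd = 0.5)
    f_sma <- allometry(t2, "sma")
    f_slr <- allometry(t2, "slr")
    r <- cor(t2$x, t2$y)
    expect_equal(unname(coef(f_sma)["x"]), unname(coef(f_slr)["x"]) / r,
                 tolerance = 1e-10)
    # scale y to equal variance: |b| = 1 regardless of correlation
    t3 <- t2
    t3$y <- t3$y * sd(t3$x) / sd(t3$y)
    expect_equal(abs(unname(coef(allometry(t3, "sma"))["x"])), 1, tolerance = 1e-10)
  }
})

test_that("MA slope equals the leading-eigenvector slope of the covariance", {
  tab <- data.frame(species = c("a", "b", "c"), x = c(0, 1, 2), y = c(0, 2, 4))
  expect_equal(unname(coef(allometry(tab, "ma"))["x"]), 2, tolerance = 1e-12)

  for (seed in 1:5) {
    t2 <- make_line_table(n = 25, seed = seed + 10, sd = 0.6)
    b <- unname(coef(allometry(t2, "ma"))["x"])
    ev <- eigen(cov(cbind(t2$x, t2$y)), symmetric = TRUE)$vectors[, 1]
    expect_equal(b, ev[2] / ev[1], tolerance = 1e-10)
  }
  # symmetric case: equal variances, positive covariance -> slope 1
  set.seed(3)
  u <- rnorm(50); v <- u + rnorm(50)
  su <- scale(u)[, 1]; sv <- scale(v)[, 1]
  tabs <- data.frame(species = paste0("s", 1:50), x = su, y = sv)
  expect_equal(unname(coef(allometry(tabs, "ma"))["x"]), 1, tolerance = 1e-9)
})

test_that("residual identities: vertical residuals average zero, line passes (xbar, ybar)", {
  t2 <- make_line_table(n = 50, seed = 2, sd = 0.4)
  for (m in c("slr", "mslr", "sma", "ma")) {
    fit <- allometry(t2, m)
    expect_lt(abs(mean(residuals(fit))), 1e-10)
  }
})

test_that("b_slr <= |b_sma| with equality iff r^2 = 1", {
  t2 <- make_line_table(n = 40, seed = 5, sd = 0.5)
  expect_lt(abs(coef(allometry(t2, "slr"))["x"]),
            abs(coef(allometry(t2, "sma"))["x"]))
  t2$y <- 1 + 2 * t2$x
  expect_equal(unname(coef(allometry(t2, "slr"))["x"]),
               unname(coef(allometry(t2, "sma"))["x"]), tolerance = 1e-10)
})

test_that("global mass rescaling shifts only the intercept; residuals unchanged", {
  t2 <- make_line_table(n = 40, seed = 7, sd = 0.3)
  k <- log10(7.3)                        # multiply all raw masses by 7.3
  for (m in c("slr", "sma", "ma")) {
    f1 <- allometry(t2, m)
    t3 <- t2
    t3$x <- t3$x + k                     # adult mass rescaled
    f2 <- allometry(t3, m)
    expect_equal(unname(coef(f2)["x"]), unname(coef(f1)["x"]), tolerance = 1e-8)
    expect_equal(residuals(f2), residuals(f1), tolerance = 1e-8)
  }
})

test_that("back-transformation to allometric form matches direct evaluation", {
  t2 <- make_line_table(n = 30, seed = 9)
  fit <- allometry(t2, "slr")
  form <- allometric_form(fit)
  expect_equal(form$constant, 10^coef(fit)[["(Intercept)"]])
  m_a <- c(10, 1000, 1e6)
  expect_equal(predict(form, m_a),
               10^predict(fit, data.frame(x = log10(m_a))), tolerance = 1e-12)
  # two-predictor form needs the duration
  fitm <- allometry(t2, "mslr")
  formm <- allometric_form(fitm)
  expect_error(predict(formm, 1000), class = "allomi_validation_error")
  expect_equal(predict(formm, 1000, 100),
               10^(coef(fitm)[["(Intercept)"]] + 3 * coef(fitm)[["x"]] +
                     2 * coef(fitm)[["z"]]), tolerance = 1e-12)
})

test_that("printed-precision constants reproduce the reference formulas", {
  # a = -0.196 -> a' = 0.637 and the two-predictor forms
  expect_equal(signif(10^-0.196, 3), 0.637)
  expect_equal(signif(10^0.664, 3), 4.61)
  expect_equal(signif(10^0.204, 3), 1.60)
  # direct evaluation of the single-predictor formula at 1 kg
  expect_equal(0.637 * 1000^0.778, 137.5, tolerance = 0.05)
  # two-predictor formula at 1 kg, 100 d
  expect_equal(1.60 * 1000^0.836 * 100^-0.199, 206.1, tolerance = 0.05)
})

test_that("confidence intervals use the stated closed forms", {
  t2 <- make_line_table(n = 60, seed = 11, sd = 0.4)
  fit <- allometry(t2, "slr")
  lmci <- confint(lm(y ~ x, t2))
  expect_equal(unname(fit$ci), unname(lmci), tolerance = 1e-10)

  f_sma <- allometry(t2, "sma")
  n <- 60; r2 <- f_sma$r_squared
  B <- qf(0.95, 1, n - 2) * (1 - r2) / (n - 2)
  b <- coef(f_sma)[["x"]]
  expect_equal(sort(unname(f_sma$ci["x", ])),
               sort(b * (sqrt(B + 1) + c(-1, 1) * sqrt(B))), tolerance = 1e-10)
})

test_that("simulate() is reproducible and centred on the fitted line", {
  t2 <- make_line_table(n = 50, seed = 13, sd = 0.3)
  fit <- allometry(t2, "slr")
  s1 <- simulate(fit, nsim = 3, seed = 99)
  s2 <- simulate(fit, nsim = 3, seed = 99)
  expect_identical(s1, s2)
  big <- simulate(fit, nsim = 400, seed = 1)
  expect_equal(rowMeans(big), fitted(fit), tolerance = 0.1)
})
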