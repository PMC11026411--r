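# The mixed-model engine is checked against closed-form oracles on small
# instances, then against its own generative model (simulate_dataset).

test_that("marginal log-likelihood matches the direct GLS matrix oracle (gamma = 0)", {
  for (seed in c(1, 2, 3)) {
    n <- 10
    tree <- simulate_tree(n, seed)
    set.seed(seed + 100)
    d <- data.frame(species = tree$tip.label, x = runif(n, 1, 6))
    d$y <- 0.2 + 0.8 * d$x + rnorm(n, 0, 0.3)
    corr <- bm_correlation(tree, d$species)
    for (Lam in c(0.3, 0.9)) {
      rhoL <- pagel_scale(corr, Lam)$rho
      lambda <- 0.04; delta0 <- -2; delta1 <- 0.08
      V <- lambda * rhoL + diag(exp(delta0 + delta1 * d$x))
      beta <- c(0.15, 0.78)
      e <- d$y - beta[1] - beta[2] * d$x
      ll <- dhglm_loglik(list(beta = beta, lambda = lambda, delta0 = delta0,
                              delta1 = delta1, gamma = 0),
                         d, tree, Lambda = Lam)
      expect_equal(ll, mvn_loglik_oracle(e, V), tolerance = 1e-6)
    }
  }
})

test_that("with lambda = 0 and gamma = 0 the likelihood is a sum of independent Gaussians", {
  n <- 8
  tree <- simulate_tree(n, 4)
  set.seed(5)
  d <- data.frame(species = tree$tip.label, x = runif(n, 1, 6))
  d$y <- 0.1 + 0.7 * d$x + rnorm(n, 0, 0.2)
  beta <- c(0.1, 0.7)
  e <- d$y - beta[1] - beta[2] * d$x
  ll <- dhglm_loglik(list(beta = beta, lambda = 0, delta0 = -1.5,
                          delta1 = 0.1, gamma = 0), d, tree, Lambda = 0.5)
  expect_equal(ll, sum(dnorm(e, 0, sqrt(exp(-1.5 + 0.1 * d$x)), log = TRUE)),
               tolerance = 1e-8)
})

test_that("GLS coefficients from the engine match the explicit-inverse oracle", {
  n <- 12
  tree <- simulate_tree(n, 6)
  set.seed(7)
  d <- data.frame(species = tree$tip.label, x = runif(n, 1, 6))
  d$y <- 0.2 + 0.8 * d$x + rnorm(n, 0, 0.3)
  X <- cbind(1, d$x)
  rhoL <- pagel_scale(bm_correlation(tree, d$species), 0.7)$rho
  V <- 0.05 * rhoL + diag(exp(-2 + 0.1 * d$x))
  beta_oracle <- solve(t(X) %*% solve(V) %*% X, t(X) %*% solve(V) %*% d$y)
  ch <- chol(V)
  expect_equal(unname(allomi:::gls_beta(ch, X, d$y)), drop(beta_oracle),
               tolerance = 1e-6)
})

test_that("a quasi-independent tip contributes its own likelihood term", {
  tree <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);")
  d <- data.frame(species = c("A", "B", "C", "D"),
                  x = c(1, 2, 3, 4), y = c(1.1, 2.1, 2.8, 9))
  beta <- c(0, 1)
  base <- dhglm_loglik(list(beta = beta, lambda = 0.05, delta0 = log(4),
                            delta1 = 0, gamma = 0),
                       d, tree, Lambda = 1)
  d3 <- d[1:3, ]
  tree3 <- ape::drop.tip(tree, "D")
  part <- dhglm_loglik(list(beta = beta, lambda = 0.05, delta0 = log(4),
                            delta1 = 0, gamma = 0),
                       d3, tree3, Lambda = 1)
  own <- dnorm(9 - 4, 0, sqrt(0.05 + 4), log = TRUE)
  expect_equal(base, part + own, tolerance = 0.02)
})

test_that("variance parameters must be non-negative and Lambda in [0, 1]", {
  tree <- simulate_tree(10, 8)
  d <- data.frame(species = tree$tip.label, x = 1:10, y = rnorm(10))
  p <- list(beta = c(0, 0), lambda = -1, delta0 = 0, delta1 = 0, gamma = 0)
  expect_error(dhglm_loglik(p, d, tree, Lambda = 0.5), class = "allomi_domain_error")
  expect_error(allometry(d, "plmm", tree = tree, lambda_pagel = 1.5),
               class = "allomi_domain_error")
})

test_that("under an OLS generative model the mixed fit matches OLS fixed effects", {
  cfg <- sim_config(n_species = 50, seed = 10, lambda = 0, gamma = 0,
                    delta1 = 0, Lambda = 0.5)
  sim <- simulate_dataset(cfg)
  ols <- allometry(sim$table, "mslr")
  mix <- allometry(sim$table, "mplmm", tree = sim$tree, lambda_pagel = 0.5)
  # the mixed fit re-estimates the residual-variance slope from noise, so
  # its GLS weights differ slightly from OLS: agreement within 1 OLS SE
  expect_true(all(abs(coef(mix) - coef(ols)) < sqrt(diag(ols$vcov))))
  expect_true(all(mix$phi > 0))
  expect_true(mix$lambda_phy < 0.01)
})

test_that("a star phylogeny flags Pagel's Lambda as unidentifiable", {
  star <- ape::stree(12, type = "star")
  star$edge.length <- rep(1, nrow(star$edge))
  set.seed(11)
  d <- data.frame(species = star$tip.label, x = runif(12, 1, 6))
  d$y <- 0.2 + 0.8 * d$x + rnorm(12, 0, 0.3)
  fit <- allometry(d, "plmm", tree = star)
  expect_true(fit$lambda_unidentifiable)
})

test_that("fit preconditions: minimum size and tree coverage", {
  tree <- simulate_tree(12, 12)
  d <- data.frame(species = tree$tip.label[1:8], x = 1:8, y = rnorm(8))
  expect_error(allometry(d, "plmm", tree = tree), class = "allomi_validation_error")
  d2 <- data.frame(species = c(tree$tip.label[1:11], "missing_sp"),
                   x = 1:12, y = rnorm(12))
  expect_error(allometry(d2, "plmm", tree = tree), "missing_sp",
               class = "allomi_validation_error")
  expect_error(allometry(d2[1:11, ], "plmm", tree = NULL),
               class = "allomi_validation_error")
})

test_that("marginal and conditional predictions differ by the predicted random effect", {
  cfg <- sim_config(n_species = 40, seed = 13, lambda = 0.1, Lambda = 1)
  sim <- simulate_dataset(cfg)
  fit <- allometry(sim$table, "mplmm", tree = sim$tree, lambda_pagel = 1)
  marg <- predict(fit)
  cond <- predict(fit, type = "conditional")
  expect_equal(cond - marg, fit$ranef_phylo, tolerance = 1e-10)
  # same identity through newdata for a subset of species
  nd <- sim$table[5:9, ]
  expect_equal(predict(fit, nd, type = "conditional") -
                 predict(fit, nd, type = "marginal"),
               fit$ranef_phylo[5:9], tolerance = 1e-10)
  expect_error(predict(fit, data.frame(x = 1), type = "conditional"),
               class = "allomi_validation_error")
  expect_error(predict(fit, data.frame(species = "nope", x = 1, z = 1),
                       type = "conditional"), class = "allomi_validation_error")
  # MI uses marginal predictions: residual identity
  mi <- maternal_investment(fit)
  expect_equal(mi$MI - (sim$table$y - cond), fit$ranef_phylo, tolerance = 1e-10)
})

test_that("missing duration in newdata is an argument error for two-predictor fits", {
  cfg <- sim_config(n_species = 30, seed = 14)
  sim <- simulate_dataset(cfg)
  fit <- allometry(sim$table, "mplmm", tree = sim$tree, lambda_pagel = 0.9)
  expect_error(predict(fit, data.frame(x = 3)), class = "allomi_validation_error")
  expect_equal(predict(fit, data.frame(x = 3, z = 2)),
               sum(coef(fit) * c(1, 3, 2)), tolerance = 1e-12)
})

test_that("Pagel profile: argmax beats grid points; strong signal pushes Lambda high", {
  cfg <- sim_config(n_species = 60, seed = 15, lambda = 0.3, Lambda = 1,
                    gamma = 0, delta1 = 0, delta0 = -4)
  sim <- simulate_dataset(cfg)
  prof <- profile_pagel(sim$table, sim$tree, duration = TRUE,
                        grid = c(0, 0.25, 0.5, 0.75, 1))
  # tolerance reflects the inner fit's own convergence tolerance (1e-6
  # relative on a criterion of magnitude ~10-100)
  expect_gte(prof$logLik + 1e-3, max(prof$profile[, "ll"]))
  expect_gt(prof$Lambda, 0.7)

  # white noise: the fitted phylogenetic covariance is negligible
  cfg0 <- sim_config(n_species = 40, seed = 16, lambda = 0, Lambda = 0.5,
                     gamma = 0, delta1 = 0)
  sim0 <- simulate_dataset(cfg0)
  fit0 <- allometry(sim0$table, "mplmm", tree = sim0$tree)
  expect_lt(fit0$lambda_phy * fit0$Lambda, 0.02)
})

test_that("likelihood at the optimum is at least the likelihood at the initialisation", {
  cfg <- sim_config(n_species = 40, seed = 17)
  sim <- simulate_dataset(cfg)
  fit <- allometry(sim$table, "mplmm", tree = sim$tree, lambda_pagel = 0.9)
  ols <- lm(y ~ x + z, sim$table)
  init <- list(beta = unname(coef(ols)),
               lambda = 0.5 * var(residuals(ols)),
               delta0 = log(mean(residuals(ols)^2)), delta1 = 0, gamma = 0.01)
  ll_init <- dhglm_loglik(init, sim$table, sim$tree, Lambda = 0.9,
                          duration = TRUE)
  expect_gte(fit$logLik, ll_init - 1e-6)
})

test_that("profile likelihood is invariant to species reordering", {
  cfg <- sim_config(n_species = 30, seed = 18)
  sim <- simulate_dataset(cfg)
  f1 <- allometry(sim$table, "mplmm", tree = sim$tree, lambda_pagel = 0.8)
  perm <- sample(nrow(sim$table))
  f2 <- allometry(sim$table[perm, ], "mplmm", tree = sim$tree, lambda_pagel = 0.8)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-5)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-5)
})

test_that("group-specific slopes: validation and recovery of distinct scalings", {
  cfg <- sim_config(n_species = 120, seed = 19, lambda = 0.02, Lambda = 0.9,
                    gamma = 0.02,
                    group_slopes = list(mass = c(0.848, 0.778)))
  sim <- simulate_dataset(cfg)
  counts <- table(sim$table$group)
  skip_if(min(counts) < 10, "unbalanced root split for this tree")
  fit <- allometry(sim$table, "mplmm", tree = sim$tree, groups = "group",
                   interactions = "mass", lambda_pagel = 0.9)
  cf <- coef(fit)
  bA <- cf[["x"]]
  bB <- cf[["x"]] + cf[[grep(":x$|^x:", names(cf), value = TRUE)]]
  expect_equal(bA, 0.848, tolerance = 0.06)
  expect_equal(bB, 0.778, tolerance = 0.06)

  base <- allometry(sim$table, "mplmm", tree = sim$tree, groups = "group",
                    interactions = character(0), lambda_pagel = 0.9)
  expect_lt(length(coef(base)), length(coef(fit)))

  one <- sim$table
  one$group <- "A"
  expect_error(allometry(one, "mplmm", tree = sim$tree, groups = "group"),
               class = "allomi_validation_error")
  small <- sim$table
  small$group[2:nrow(small)] <- "A"
  small$group[1] <- "B"
  expect_error(allometry(small, "mplmm", tree = sim$tree, groups = "group"),
               "B", class = "allomi_validation_error")
})
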