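test_that("with no random factors fit_lmm is exactly Gaussian OLS", {
  set.seed(21)
  n <- 60
  X <- cbind("(Intercept)" = 1, x1 = runif(n), x2 = rnorm(n))
  y <- 2 + 3 * X[, 2] - X[, 3] + rnorm(n)
  f <- fit_lmm(y, X, list(), "ML")
  ols <- lm(y ~ X[, 2] + X[, 3])
  expect_equal(unname(f$beta), unname(coef(ols)), tolerance = 1e-10)
  # Gaussian ML loglik with sigma2 = RSS/n
  s2 <- sum(resid(ols)^2) / n
  ll <- -0.5 * n * (log(2 * pi) + log(s2) + 1)
  expect_equal(f$loglik, ll, tolerance = 1e-8)
  expect_equal(f$aic, 2 * 4 - 2 * ll)
})

test_that("independent data: LMM loglik collapses to the OLS loglik", {
  set.seed(22)
  n <- 120
  X <- cbind("(Intercept)" = 1, x = runif(n))
  y <- 1 + 2 * X[, 2] + rnorm(n)   # truth has no group structure
  id <- sample(sprintf("i%d", 1:40), n, TRUE)
  yr <- sample(2000:2009, n, TRUE)
  f <- fit_lmm(y, X, list(individual = id, year = yr), "ML")
  ols <- fit_lmm(y, X, list(), "ML")
  expect_lt(ols$loglik - f$loglik, 1e-4)   # boundary attained or exceeded
  expect_gte(f$loglik, ols$loglik - 1e-6)  # never worse than OLS
  expect_equal(unname(f$beta), unname(ols$beta), tolerance = 1e-3)
})

test_that("balanced one-way variance components match closed forms", {
  set.seed(23)
  a <- 12; m <- 5
  g <- rep(sprintf("g%02d", 1:a), each = m)
  y <- 10 + rep(rnorm(a, 0, 2), each = m) + rnorm(a * m, 0, 1)
  X <- matrix(1, a * m, 1, dimnames = list(NULL, "(Intercept)"))
  gm <- tapply(y, g, mean)
  MSB <- m * sum((gm - mean(y))^2) / (a - 1)
  MSW <- sum((y - gm[g])^2) / (a * (m - 1))
  fml <- fit_lmm(y, X, list(grp = g), "ML")
  expect_equal(unname(fml$sigma2),
               c((MSB * (a - 1) / a - MSW) / m, MSW), tolerance = 1e-3)
  frl <- fit_lmm(y, X, list(grp = g), "REML")
  expect_equal(unname(frl$sigma2), c((MSB - MSW) / m, MSW),
               tolerance = 1e-3)
})

test_that("crossed-design estimates agree with the lme4 oracle", {
  skip_if_not_installed("lme4")
  d <- sim_lmm_data(n = 150, seed = 24)
  X <- design3(d)
  for (meth in c("ML", "REML")) {
    f <- fit_lmm(d$epigenetic_age, X,
                 list(individual = d$individual_id,
                      year = d$year_sampled), meth)
    l4 <- lme4::lmer(
      epigenetic_age ~ bond_strength_norm + mean_male_group_size +
        chronological_age + (1 | individual_id) + (1 | year_sampled),
      data = d, REML = (meth == "REML"),
      control = lme4::lmerControl(check.conv.singular = "ignore"))
    expect_equal(unname(f$beta), unname(lme4::fixef(l4)),
                 tolerance = 1e-5)
    expect_equal(f$loglik, as.numeric(logLik(l4)), tolerance = 1e-5)
    vc <- as.data.frame(lme4::VarCorr(l4))
    expect_equal(unname(f$sigma2[c("individual", "year", "resid")]),
                 vc$vcov[match(c("individual_id", "year_sampled",
                                 "Residual"), vc$grp)],
                 tolerance = 1e-4)
    expect_equal(unname(f$se_beta),
                 unname(sqrt(diag(as.matrix(vcov(l4))))), tolerance = 1e-4)
  }
})

test_that("loglik is invariant to row order and factor label swap", {
  d <- sim_lmm_data(n = 100, seed = 25)
  X <- design3(d)
  f1 <- fit_lmm(d$epigenetic_age, X,
                list(individual = d$individual_id,
                     year = d$year_sampled), "ML")
  perm <- sample(nrow(d))
  f2 <- fit_lmm(d$epigenetic_age[perm], X[perm, ],
                list(individual = d$individual_id[perm],
                     year = d$year_sampled[perm]), "ML")
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  f3 <- fit_lmm(d$epigenetic_age, X,
                list(year = d$year_sampled,
                     individual = d$individual_id), "ML")
  expect_equal(f1$loglik, f3$loglik, tolerance = 1e-6)
  expect_equal(unname(f1$sigma2["individual"]),
               unname(f3$sigma2["individual"]), tolerance = 1e-4)
})

test_that("aic arithmetic and reproducibility", {
  d <- sim_lmm_data(n = 80, seed = 26)
  X <- design3(d)
  f <- fit_lmm(d$epigenetic_age, X,
               list(individual = d$individual_id), "ML")
  expect_equal(aic(f), 2 * f$k - 2 * f$loglik)
  expect_identical(f$k, ncol(X) + 2L)
  f2 <- fit_lmm(d$epigenetic_age, X,
                list(individual = d$individual_id), "ML")
  expect_identical(aic(f), aic(f2))
  # a pure-noise predictor increases AIC in most replicates
  worse <- sapply(1:20, function(s) {
    set.seed(300 + s)
    Xn <- cbind(X, noise = rnorm(nrow(X)))
    fit_lmm(d$epigenetic_age, Xn,
            list(individual = d$individual_id), "ML")$aic > f$aic
  })
  expect_gt(mean(worse), 0.6)
  expect_error(fit_lmm(d$epigenetic_age, cbind(X, X[, 2]),
                       list(), "ML"), "rank")
})

test_that("Satterthwaite p-values agree with normal at large n", {
  d <- sim_lmm_data(n = 400, n_ind = 150, seed = 27)
  X <- design3(d)
  f <- fit_lmm(d$epigenetic_age, X,
               list(individual = d$individual_id,
                    year = d$year_sampled), "REML")
  ps <- fixed_effect_pvalues(f, "satterthwaite")
  pn <- fixed_effect_pvalues(f, "normal")
  # t and z tails converge slowly in relative terms; require 10%
  # relative agreement or a vanishing absolute difference
  agree <- abs(ps$p_value - pn$p_value) <=
    pmax(0.1 * pn$p_value, 5e-4)
  expect_true(all(agree))
  expect_true(all(ps$df > 100))  # large-n dfs are large
  expect_true(all(ps$df > 0))
  # normal method: a zero t-statistic gives p = 1
  expect_equal(2 * pnorm(0), 1)
})

test_that("standardized coefficients scale correctly", {
  d <- sim_lmm_data(n = 120, seed = 28)
  X <- design3(d)
  f <- fit_lmm(d$epigenetic_age, X,
               list(individual = d$individual_id), "REML")
  std <- standardized_coefficients(f)
  j <- std$term == "bond_strength_norm"
  expect_equal(std$std_estimate[j],
               std$estimate[j] * sd(d$bond_strength_norm))
  # rescaling a predictor x10 leaves its standardized estimate unchanged
  X10 <- X; X10[, "bond_strength_norm"] <- X[, "bond_strength_norm"] * 10
  f10 <- fit_lmm(d$epigenetic_age, X10,
                 list(individual = d$individual_id), "REML")
  std10 <- standardized_coefficients(f10)
  expect_equal(std10$std_estimate[j], std$std_estimate[j],
               tolerance = 1e-6)
  # the reported effect sizes: b * SD reproduces the printed standardized
  # estimates within 0.05 (rounding of the printed SDs)
  expect_lt(abs(-9.75 * 0.17 - (-1.69)), 0.05)
  expect_lt(abs(0.90 * 1.44 - 1.33), 0.05)
  Xc <- cbind(X, const = 5)
  fc <- fit_lmm(d$epigenetic_age, Xc[, -1],
                list(individual = d$individual_id), "REML")
  expect_error(standardized_coefficients(fc), "zero-variance")
})

test_that("partial residuals reproduce component-plus-residual values", {
  set.seed(29)
  n <- 80
  X <- cbind("(Intercept)" = 1, x1 = runif(n), x2 = rnorm(n))
  y <- 1 + 2 * X[, 2] - 3 * X[, 3] + rnorm(n)
  f <- fit_lmm(y, X, list(), "ML")
  pr <- partial_residuals(f, "x1")
  # textbook component-plus-residual from lm
  ols <- lm(y ~ X[, 2] + X[, 3])
  expect_equal(pr$partial_residual,
               unname(coef(ols)[2] * X[, 2] + resid(ols)),
               tolerance = 1e-8)
  # slope of partial residuals on x_j equals the coefficient
  sl <- coef(lm(pr$partial_residual ~ pr$x))[2]
  expect_equal(unname(sl), unname(f$beta["x1"]), tolerance = 1e-6)
  # mixed model: same slope identity through the BLUP-adjusted residuals
  d <- sim_lmm_data(n = 100, seed = 30)
  Xd <- design3(d)
  fm <- fit_lmm(d$epigenetic_age, Xd,
                list(individual = d$individual_id,
                     year = d$year_sampled), "REML")
  prm <- partial_residuals(fm, "bond_strength_norm")
  slm <- coef(lm(prm$partial_residual ~ prm$x))[2]
  expect_equal(unname(slm), unname(fm$beta["bond_strength_norm"]),
               tolerance = 1e-6)
  expect_error(partial_residuals(fm, "nope"), "not in the model")
})

test_that("collinearity check: VIFs and sentinel", {
  set.seed(31)
  n <- 50
  x1 <- rnorm(n); x2 <- rnorm(n)
  x1 <- x1 - mean(x1); x2 <- resid(lm(x2 ~ x1)) # orthogonalized
  cc <- collinearity_check(cbind(a = x1, b = x2))
  expect_equal(unname(cc$vif), c(1, 1), tolerance = 1e-10)
  cc2 <- collinearity_check(cbind(a = x1, b = 2 * x1, c = x2))
  expect_true(any(is.infinite(cc2$vif)))
  # brute-force oracle on a correlated fixture
  X <- cbind(a = rnorm(n), b = rnorm(n))
  X <- cbind(X, c = 0.7 * X[, 1] + 0.5 * rnorm(n))
  cc3 <- collinearity_check(X)
  for (j in 1:3) {
    r2 <- summary(lm(X[, j] ~ X[, -j]))$r.squared
    expect_equal(unname(cc3$vif[j]), 1 / (1 - r2), tolerance = 1e-10)
  }
})
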