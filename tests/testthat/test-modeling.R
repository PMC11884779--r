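# Mixed-model fitting: identifiability, closed-form oracles, model
# comparison, variance decomposition, subset fits and the Welch tests.

test_that("noise-free synthetic data is recovered exactly", {
  sc <- synth_scenario(seed = 5, var_u = 0, sigma2 = 1e-14)
  dat <- synth_features(sc)
  fit <- rate_lmm(data = dat, scale = FALSE)
  truth <- sc$beta[c("(Intercept)", "PC1", "PC2", "min_steps", "pyr_diff", "PC1:PC2")]
  expect_equal(unname(coef(fit)), unname(truth), tolerance = 1e-6)
  # with negligible noise the fit reduces to least squares
  ols <- lm(log_rate ~ PC1 * PC2 + min_steps + pyr_diff, data = dat)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-6)
})

test_that("REML matches closed-form ANOVA estimators on a balanced design", {
  set.seed(42)
  g <- 15L; n <- 6L
  grp <- rep(sprintf("g%02d", 1:g), each = n)
  y <- rep(rnorm(g, 0, 1.5), each = n) + rnorm(g * n, 0, 1)
  dat <- data.frame(y = y, grp = grp)
  fit <- rate_lmm(y ~ 1, dat, random = "grp", scale = FALSE)
  av <- anova(aov(y ~ factor(grp), data = dat))
  msb <- av[["Mean Sq"]][1]; msw <- av[["Mean Sq"]][2]
  expect_equal(unname(fit$sigma2), msw, tolerance = 1e-6)
  expect_equal(unname(fit$varcor[["grp"]]), (msb - msw) / n, tolerance = 1e-6)
  expect_equal(unname(coef(fit)[1]), mean(y), tolerance = 1e-8)
})

test_that("fit validates its inputs", {
  dat <- synth_features(synth_scenario(seed = 2))
  expect_error(rate_lmm(log_rate ~ PC1, dat, random = "nope"), "not in data")
  expect_error(rate_lmm(log_rate ~ missing_col, dat), "covariate")
  dat2 <- dat; dat2$log_rate[1] <- NA
  expect_error(rate_lmm(data = dat2), "non-finite")
  dat3 <- dat; dat3$dup <- dat3$PC1
  expect_error(rate_lmm(log_rate ~ PC1 + dup, dat3), "aliased|rank")
  dat4 <- dat; dat4$flat <- 1
  expect_error(rate_lmm(log_rate ~ PC1 + flat, dat4, scale = TRUE), "constant")
})

test_that("coefficient table and fit statistics are internally consistent", {
  dat <- synth_features(synth_scenario(seed = 3))
  fit <- rate_lmm(data = dat)
  expect_equal(fit$coefficients$t, fit$coefficients$estimate / fit$coefficients$se)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$n_params)
  expect_gt(fit$sigma2, 0)
  expect_true(all(fit$varcor >= 0))
  expect_true(fit$r2_marginal >= 0 && fit$r2_marginal <= fit$r2_conditional)
  expect_lte(fit$r2_conditional, 1)
  # Satterthwaite dfs live in (0, n - p]
  p <- nrow(fit$coefficients)
  expect_true(all(fit$coefficients$df > 0))
  expect_true(all(fit$coefficients$df <= fit$n - p + 1e-8))
  expect_equal(marginal_r2(fit), fit$r2_marginal)
  expect_equal(marginal_r2(fit, conditional = TRUE), fit$r2_conditional)
})

test_that("Satterthwaite df shrink as the random-effect variance grows", {
  dfs <- vapply(c(0.01, 0.5), function(vu) {
    dat <- synth_features(synth_scenario(seed = 7, var_u = vu))
    fit <- rate_lmm(data = dat, scale = FALSE)
    fit$coefficients$df[fit$coefficients$term == "min_steps"]
  }, numeric(1))
  expect_lt(dfs[2], dfs[1])
})

test_that("model comparison handles degenerate and proper nesting", {
  dat <- synth_features(synth_scenario(seed = 4))
  full <- rate_lmm(data = dat)
  same <- compare_models(full, full)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  red <- rate_lmm(log_rate ~ PC1 + PC2 + min_steps + pyr_diff, dat)
  cmp <- compare_models(full, red)
  expect_equal(cmp$df, 1L)
  expect_gte(cmp$chi2, 0)
  expect_error(compare_models(red, full), "not nested")
  # AIC and LRT agree in sign: delta_aic > 0 iff chi2 > 2 df
  expect_equal(cmp$delta_aic > 0, cmp$chi2 > 2 * cmp$df)
})

test_that("a strong true interaction is detected with tiny p-values", {
  sc <- synth_scenario(beta = c("(Intercept)" = 0, PC1 = -0.4, PC2 = -0.3,
                                min_steps = -0.4, pyr_diff = -0.2,
                                "PC1:PC2" = 0.4),
                       sigma2 = 0.1, seed = 8)
  for (r in 1:3) {
    dat <- synth_features(sc, noise_seed = 8 + r)
    full <- rate_lmm(data = dat, scale = FALSE, REML = FALSE)
    red <- rate_lmm(log_rate ~ PC1 + PC2 + min_steps + pyr_diff, dat,
                    scale = FALSE, REML = FALSE)
    expect_lt(compare_models(full, red)$p, 1e-6)
  }
})

test_that("marginal R2 has the right limits", {
  # noise-free, no random effects: essentially all variance is fixed
  dat <- synth_features(synth_scenario(seed = 5, var_u = 0, sigma2 = 1e-14))
  fit <- rate_lmm(data = dat, scale = FALSE)
  expect_gt(fit$r2_marginal, 0.999)
  # intercept-only fixed part: marginal R2 is exactly zero
  set.seed(31)
  dat2 <- dat
  dat2$log_rate <- rnorm(nrow(dat2))
  fit0 <- rate_lmm(log_rate ~ 1, dat2, scale = FALSE)
  expect_equal(fit0$r2_marginal, 0)
})

test_that("known variance shares are recovered by the R2 decomposition", {
  # fixed 0.5, random 0.3, residual 0.2 of total variance, averaged over seeds
  r2 <- vapply(1:10, function(s) {
    dat <- synth_features(synth_scenario(seed = 100 + s))
    # rescale: pick var_u/sigma2 to hit the target shares given var(Xb)
    eta <- with(dat, -0.4 * PC1 - 0.3 * PC2 - 0.4 * min_steps -
                  0.2 * pyr_diff + 0.08 * PC1 * PC2)
    vf <- var(eta)
    sc <- synth_scenario(var_u = 0.3 * vf / 0.5 / 2, sigma2 = 0.2 * vf / 0.5,
                         seed = 100 + s)
    fit <- rate_lmm(data = synth_features(sc), scale = FALSE)
    fit$r2_marginal
  }, numeric(1))
  expect_lt(abs(mean(r2) - 0.5), 0.05)
})

test_that("per-step subset fits partition the data and respect linearity", {
  dat <- synth_features(synth_scenario(seed = 6))
  sizes <- vapply(1:3, function(s) fit_by_steps(dat, s)$n, numeric(1))
  expect_equal(sum(sizes), nrow(dat))
  met <- pair_metric_table()
  expect_equal(unname(sizes), as.numeric(2 * table(met$min_steps)))
  expect_error(fit_by_steps(dat, 2, formula = log_rate ~ PC1 + min_steps),
               "min_steps")
  # noise-free data: subset slopes equal the generating slopes exactly
  d0 <- synth_features(synth_scenario(seed = 6, var_u = 0, sigma2 = 1e-14))
  f1 <- fit_by_steps(d0, 1, scale = FALSE)
  cf <- coef(f1)
  expect_equal(cf[["PC1"]], -0.4, tolerance = 1e-5)
  expect_equal(cf[["PC2"]], -0.3, tolerance = 1e-5)
  expect_equal(cf[["PC1:PC2"]], 0.08, tolerance = 1e-5)
})

test_that("Welch ANOVA reduces to the squared Welch t for two groups", {
  set.seed(9)
  x <- rnorm(30, 0, 1); y <- rnorm(25, 0.5, 2)
  wa <- welch_anova(c(x, y), rep(c("a", "b"), c(30, 25)))
  wt <- welch_t_test(x, y)
  expect_equal(wa$F, wt$t^2, tolerance = 1e-10)
  expect_equal(wa$p, wt$p, tolerance = 1e-10)
  expect_equal(wa$df2, wt$df, tolerance = 1e-10)
})

test_that("Welch ANOVA separates shifted groups and validates input", {
  set.seed(10)
  vals <- c(rnorm(40), rnorm(40), rnorm(40, 5))
  grp <- rep(c("a", "b", "c"), each = 40)
  expect_lt(welch_anova(vals, grp)$p, 1e-6)
  expect_error(welch_anova(1:4, c("a", "a", "a", "b")), "at least 2")
  expect_error(welch_anova(c(1, 1, 2, 3), c("a", "a", "b", "b")), "zero within-group")
  expect_error(welch_anova(1:4, rep("a", 4)), "2 groups")
})

test_that("Welch t matches the textbook formula and its identities", {
  set.seed(11)
  x <- rnorm(18, 1, 2); y <- rnorm(23, 0, 0.7)
  wt <- welch_t_test(x, y)
  # independent textbook computation
  se2 <- var(x) / length(x) + var(y) / length(y)
  t_manual <- (mean(x) - mean(y)) / sqrt(se2)
  df_manual <- se2^2 / (var(x)^2 / (length(x)^2 * (length(x) - 1)) +
                        var(y)^2 / (length(y)^2 * (length(y) - 1)))
  p_manual <- 2 * pt(-abs(t_manual), df_manual)
  expect_equal(wt$t, t_manual, tolerance = 1e-12)
  expect_equal(wt$df, df_manual, tolerance = 1e-12)
  expect_equal(wt$p, p_manual, tolerance = 1e-12)
  # identical samples: t = 0, p = 1
  w0 <- welch_t_test(x, x)
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)
  expect_error(welch_t_test(1, 1:3), "at least 2")
})

test_that("prediction and simulation methods are coherent", {
  dat <- synth_features(synth_scenario(seed = 12))
  fit <- rate_lmm(data = dat)
  # fixed-effect predictions on the raw response scale track the data
  p <- predict(fit, newdata = dat)
  expect_equal(length(p), nrow(dat))
  expect_gt(cor(p, dat$log_rate), 0.7)
  # residuals + fitted reproduce the (scaled) response
  resp <- (dat$log_rate - fit$scaling$center["log_rate"]) /
    fit$scaling$scale["log_rate"]
  expect_equal(unname(fitted(fit) + residuals(fit)), resp, tolerance = 1e-10)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(nrow(dat), 3L))
  expect_s3_class(summary(fit), "summary.rate_lmm")
})
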