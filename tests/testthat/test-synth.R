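# Synthetic-data generator: determinism, format conformance, ground-truth
# structure, and the recovery machinery.

test_that("generation is fully deterministic under a fixed seed", {
  sc <- synth_scenario(seed = 21)
  a <- generate_exchange_model(sc)
  b <- generate_exchange_model(sc)
  expect_identical(a$model$q, b$model$q)
  expect_identical(unclass(a$properties), unclass(b$properties))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_model(a$model, f1); write_model(b$model, f2)
  expect_identical(readLines(f1), readLines(f2))
  # generation does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(generate_exchange_model(sc)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("generated models are accepted unchanged by the model readers", {
  scu <- synth_scenario(seed = 22, mode = "undirected")
  mu <- generate_exchange_model(scu)$model
  f <- withr::local_tempfile(fileext = ".dat")
  write_model(mu, f)
  back <- read_exchange_model(f)
  expect_equal(back$s, mu$s, tolerance = 1e-8)
  expect_equal(back$pi, mu$pi, tolerance = 1e-8)

  scd <- synth_scenario(seed = 22, mode = "directed")
  md <- generate_exchange_model(scd)$model
  write_model(md, f)
  backd <- read_nonreversible_model(f)
  off <- row(md$q) != col(md$q)
  expect_equal(backd$q[off], md$q[off], tolerance = 1e-8)
})

test_that("noise-free log rates are exactly linear in the features", {
  sc <- synth_scenario(seed = 23, var_u = 0, sigma2 = 1e-16)
  dat <- synth_features(sc)
  ols <- lm(log_rate ~ PC1 * PC2 + min_steps + pyr_diff, data = dat)
  expect_lt(sum(residuals(ols)^2), 1e-10)
})

test_that("property blocks are correlated within and not between", {
  cors <- vapply(1:20, function(s) {
    p <- generate_property_table(synth_scenario(seed = 300 + s))
    r <- cor(unclass(p))
    ch <- grepl("^charge_", colnames(p)); sz <- !ch
    within <- mean(c(r[ch, ch][upper.tri(r[ch, ch])],
                     r[sz, sz][upper.tri(r[sz, sz])]))
    between <- mean(r[ch, sz])
    c(within = within, between = between)
  }, numeric(2))
  expect_gt(mean(cors["within", ]), mean(cors["between", ]) + 0.3)
})

test_that("two uncorrelated properties give near-symmetric PCA fractions", {
  sc <- synth_scenario(seed = 24, n_properties = 2, rho_within = 0)
  p <- generate_property_table(sc)
  pca <- pair_pca(pairwise_differences(p))
  expect_lt(abs(pca$explained_fraction[1] - 0.5), 0.1)
})

test_that("random-intercept draws have the stated variance on average", {
  sc <- synth_scenario(seed = 25)
  vars <- vapply(1:60, function(r) {
    u <- generate_exchange_model(sc, noise_seed = 25 + r)$truth$u
    var(u$donor)
  }, numeric(1))
  mc_se <- sd(vars) / sqrt(length(vars))
  expect_lt(abs(mean(vars) - sc$var_u), 3 * mc_se)
})

test_that("overflowing coefficients raise a rescaling error", {
  sc <- synth_scenario(beta = c("(Intercept)" = 0, PC1 = -400, PC2 = -0.3,
                                min_steps = -0.4, pyr_diff = -0.2,
                                "PC1:PC2" = 0.08), seed = 26)
  expect_error(generate_exchange_model(sc), "rescale beta")
})

test_that("scenario constructor validates its arguments", {
  expect_error(synth_scenario(sigma2 = 0), "sigma2")
  expect_error(synth_scenario(var_u = -1), "var_u")
  expect_error(synth_scenario(beta = c(PC1 = 1)), "beta must name")
  expect_error(synth_scenario(rho_within = 1), "positive definite")
})

test_that("zero random-effect variance piles variance estimates at zero", {
  sc <- synth_scenario(seed = 27, var_u = 0)
  hits <- vapply(1:10, function(r) {
    fit <- rate_lmm(data = synth_features(sc, noise_seed = 27 + r), scale = FALSE)
    fit$boundary
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("doubling the residual variance inflates every slope's empirical SE", {
  base <- synth_scenario(seed = 28, sigma2 = 0.3)
  loud <- synth_scenario(seed = 28, sigma2 = 0.6)
  r1 <- recovery_experiment(base, replicates = 20)
  r2 <- recovery_experiment(loud, replicates = 20)
  slopes <- r1$table$term != "(Intercept)"
  expect_true(all(r2$table$empirical_se[slopes] > r1$table$empirical_se[slopes]))
})

test_that("recovery report has the documented shape", {
  rep <- recovery_experiment(synth_scenario(seed = 29), replicates = 6)
  expect_s3_class(rep, "recovery_report")
  expect_equal(nrow(rep$table), 6L)
  expect_named(rep$table, c("term", "truth", "bias", "rmse", "empirical_se",
                            "mean_se", "coverage"))
  expect_true(all(is.finite(rep$table$bias)))
  expect_equal(rep$failed, 0L)
})
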