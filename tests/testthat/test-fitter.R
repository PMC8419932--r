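test_that("with negligible heterogeneity the fitter matches plain IRLS", {
  lay <- swd_layout(3, 4, clusters_per_sequence = 6, n_per_cell = 40)
  gen <- swd_model("bernoulli", prevalence = 0.2,
                   time_effects = c(0.1, 0.1, 0.1), effect = 0.3,
                   sd_cluster = 0, sd_treatment = 0)
  d <- swd_simulate(lay, gen, seed = 31)
  # estimate a (tiny) random structure on iid data
  est <- swd_model("bernoulli", prevalence = 0.2,
                   time_effects = c(0.1, 0.1, 0.1), effect = 0.3,
                   sd_cluster = 0.05, sd_treatment = 0.05)
  fit <- swd_fit(d, est)
  ref <- stats::glm(y ~ factor(period) + treatment, stats::binomial, d)
  expect_true(fit$converged)
  expect_true(fit$boundary)   # variance components collapse to zero
  expect_equal(unname(fit$coef["treatment"]),
               unname(stats::coef(ref)["treatment"]), tolerance = 1e-3)
  expect_equal(fit$se_treatment,
               unname(summary(ref)$coefficients["treatment", 2]),
               tolerance = 1e-2)
})

test_that("normal random-intercept fits match an exact-likelihood oracle", {
  lay <- swd_layout(2, 3, clusters_per_sequence = 8, n_per_cell = 15)
  gen <- swd_model("normal", intercept = 1, time_effects = c(0.4, 0.2),
                   effect = 0.6, sd_cluster = 0.5, dispersion = 1)
  d <- swd_simulate(lay, gen, seed = 17)
  fit <- swd_fit(d, gen)
  oracle <- lmm_ml_oracle(d, ~ factor(period) + treatment)
  expect_true(fit$converged)
  expect_equal(unname(fit$coef), unname(oracle$beta), tolerance = 1e-5)
  expect_equal(unname(fit$sd["cluster"]^2), oracle$tau2, tolerance = 1e-4)
  expect_equal(fit$dispersion, oracle$sigma2, tolerance = 1e-4)
})

test_that("one quadrature node degenerates to the Laplace fit", {
  lay <- swd_layout(3, 4, clusters_per_sequence = 4, n_per_cell = 25)
  gen <- swd_model("bernoulli", prevalence = 0.3,
                   time_effects = c(0.1, 0.1, 0.1), effect = 0.4,
                   sd_cluster = 0.4)
  d <- swd_simulate(lay, gen, seed = 23)
  f1 <- swd_fit(d, gen, nAGQ = 1)
  f9 <- swd_fit(d, gen, nAGQ = 9)
  fA <- swd_fit(d, gen, nAGQ = 1)
  expect_equal(fA$coef, f1$coef, tolerance = 1e-10)
  # adaptive quadrature refines, but stays near, the Laplace answer
  expect_equal(unname(f9$coef["treatment"]),
               unname(f1$coef["treatment"]), tolerance = 0.02)
})

test_that("unsupported random structures are refused", {
  des <- swd_preset("ept")   # cluster intercept + per-period effects: q = 6
  d <- swd_simulate(swd_layout(4, 5, n_per_cell = 2), des$model, seed = 1)
  expect_error(swd_fit(d, des$model), "at most 2 random-effect columns")
})

test_that("the fitter is approximately unbiased for the intervention effect", {
  des <- swd_preset("sim_model1", clusters_per_sequence = 8,
                    n_per_cell = 100)
  set.seed(77)
  seeds <- sample.int(.Machine$integer.max, 40)
  est <- vapply(seeds, function(s) {
    f <- swd_fit(swd_simulate(des, seed = s), des$model)
    unname(f$coef["treatment"])
  }, numeric(1))
  mc_se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.2), 2.5 * mc_se + 0.01)
})
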