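test_that("cluster blocks have the dimensions the presets imply", {
  ept <- swd_preset("ept")
  b <- build_cluster_block(ept$layout, ept$model, 1)
  expect_equal(ncol(b$X), 1 + 4 + 1)       # intercept, 4 period dummies, tx
  expect_equal(ncol(b$Z), 1 + 5)           # cluster intercept + 5 period cols
  expect_equal(nrow(b$X), 5)               # aggregated: one row per period
  expect_equal(b$count, rep(140L, 5))
  expect_equal(colnames(b$X)[ncol(b$X)], "treatment")

  lire <- swd_preset("lire")
  b <- build_cluster_block(lire$layout, lire$model, 2)
  expect_equal(ncol(b$X), 3)               # intercept, linear time, treatment
  expect_equal(ncol(b$Z), 2 + 35)          # clinic int, clinic tx, 35 pcp
  expect_equal(nrow(b$X), 6 * 35)
  expect_equal(unname(b$D[1, 1]), 0.011^2)
  expect_equal(unname(b$D[2, 2]), 0.0054^2)
  expect_equal(unname(b$D[3, 3]), 0.0015^2)

  sim <- swd_preset("sim_model1")
  b <- build_cluster_block(sim$layout, sim$model, 1)
  expect_equal(ncol(b$Z), 2)               # intercept + treatment
})

test_that("linear predictor honours the hypothesis and treatment status", {
  lay <- swd_layout(1, 2, n_per_cell = 5)
  mod <- swd_model("bernoulli", intercept = -2, time_effects = 0,
                   effect = 0.2, sd_cluster = 0.1)
  b <- build_cluster_block(lay, mod, 1)
  expect_equal(b$meta$treatment, c(0, 1))
  expect_equal(linear_predictor(b, mod, "alternative"), c(-2, -1.8))
  expect_equal(linear_predictor(b, mod, "null"), c(-2, -2))
})

test_that("random-effect covariance assembly is validated", {
  lay <- swd_layout(2, 3, n_per_cell = 2)
  bad <- matrix(c(1, 2, 0, 1), 2, 2)
  expect_error(swd_model("bernoulli", prevalence = 0.2, effect = 0.1,
                         sd_cluster = 1, sd_treatment = 1, D = bad),
               "symmetric")
  notpsd <- rbind(c(1, 2), c(2, 1))
  expect_error(swd_model("bernoulli", prevalence = 0.2, effect = 0.1,
                         sd_cluster = 1, sd_treatment = 1, D = notpsd),
               "positive semidefinite")
  mod <- swd_model("bernoulli", prevalence = 0.2, effect = 0.1,
                   sd_cluster = 0.3, sd_time = 0.1)
  b <- build_cluster_block(lay, mod, 1)
  ev <- eigen(b$D, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) >= -1e-10)
  expect_equal(max(abs(b$D - t(b$D))), 0)
  # wrong-dimension user D is rejected against the implied structure
  mod2 <- swd_model("bernoulli", prevalence = 0.2, effect = 0.1,
                    sd_cluster = 1, D = diag(3))
  expect_error(build_cluster_block(lay, mod2, 1), "implies 1 random-effect")
})

test_that("model specification errors are caught early", {
  expect_error(swd_model("bernoulli", effect = 0.1),
               "exactly one of")
  expect_error(swd_model("bernoulli", prevalence = 0.2, intercept = -1,
                         effect = 0.1), "exactly one of")
  expect_error(swd_model("bernoulli", prevalence = 0.2, effect = 0.1,
                         time_effects = c(0.1, 0.1), time_slope = 0.2),
               "not both")
  mod <- swd_model("bernoulli", prevalence = 0.2, effect = 0.1,
                   time_effects = c(0.1, 0.1))
  lay <- swd_layout(3, 4)
  expect_error(build_cluster_block(lay, mod, 1), "length n_periods - 1")
  mod3 <- swd_model("bernoulli", prevalence = 0.2, effect = 0.1,
                    sd_cluster = 0.1, sd_subcluster = 0.2)
  expect_warning(build_cluster_block(swd_layout(2, 3), mod3, 1),
                 "single subcluster")
})

test_that("prevalence is translated to the link-scale intercept", {
  mod <- swd_model("bernoulli", prevalence = 0.08, effect = -0.3)
  expect_equal(mod$intercept, log(0.08 / 0.92))
  modn <- swd_model("normal", intercept = 3.2, effect = 1, dispersion = 4)
  expect_equal(modn$intercept, 3.2)
})
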