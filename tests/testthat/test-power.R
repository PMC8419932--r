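test_that("power formula identities and reference value hold", {
  # null effect: one-tailed size
  expect_equal(power_from_variances(0, 1, 1, 0.05), 0.025,
               tolerance = 1e-12)
  # effect at the critical value: numerator zero
  z <- qnorm(0.975)
  expect_equal(power_from_variances(z * sqrt(0.3), 0.3, 0.3, 0.05), 0.5,
               tolerance = 1e-12)
  # frozen reference computed with an independent normal CDF:
  # scipy.stats.norm.cdf((0.2 - norm.ppf(0.975)*sqrt(0.005))/sqrt(0.005))
  expect_equal(power_from_variances(0.2, 0.005, 0.005, 0.05),
               0.8074295788138213, tolerance = 1e-9)
  expect_error(power_from_variances(0.2, -1, 1, 0.05), "positive")
  expect_error(power_from_variances(0.2, 1, 1, 1.5), "alpha")
})

test_that("power is monotone in effect size and variance", {
  b <- seq(0.05, 1, by = 0.05)
  p <- vapply(b, function(x) power_from_variances(x, 0.02, 0.02, 0.05),
              numeric(1))
  expect_true(all(diff(p) > 0))
  v <- seq(0.005, 0.1, by = 0.005)
  p <- vapply(v, function(x) power_from_variances(0.3, x, x, 0.05),
              numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("design power composes variance and the power formula", {
  des <- swd_preset("sim_model1")
  # null effect gives the one-tailed size whatever the design
  m0 <- swd_model("bernoulli", prevalence = 0.12,
                  time_effects = c(0.1, 0.1, 0.1), effect = 0,
                  sd_cluster = 0.05, sd_treatment = 0.05)
  expect_equal(swd_power(des$layout, m0)$power, 0.025, tolerance = 1e-12)

  # normal/identity design agrees with the GLS oracle end to end
  lay <- swd_layout(2, 3, clusters_per_sequence = 3, n_per_cell = 5)
  mod <- swd_model("normal", intercept = 2, time_effects = c(0.3, 0.1),
                   effect = 0.9, sd_cluster = 0.4, dispersion = 1.8)
  p <- swd_power(lay, mod)
  vo <- gls_vcov_oracle(lay, mod)[4, 4]
  expect_equal(p$power, power_from_variances(0.9, vo, vo, 0.05),
               tolerance = 1e-10)

  # doubling the clusters never decreases power
  lay2 <- lay; lay2$clusters_per_sequence <- lay$clusters_per_sequence * 2L
  expect_gte(swd_power(lay2, mod)$power, p$power)
})

test_that("cell-size solver returns the smallest adequate integer", {
  des <- swd_preset("sim_model2", clusters_per_sequence = 12)
  sol <- swd_solve_n(des, target = 0.8)
  expect_gte(sol$achieved, 0.8)
  lay1 <- des$layout; lay1$n_per_cell <- sol$solution - 1L
  expect_lt(swd_power(lay1, des$model)$power, 0.8)

  # target already met at n = 1
  soft <- swd_solve_n(des, target = 0.03)
  expect_equal(soft$solution, 1L)

  # variance floor from a large random treatment effect
  hard <- swd_preset("sim_model1", sd_treatment = 1.5)
  err <- tryCatch(swd_solve_n(hard, target = 0.999, cap = 1e5),
                  swd_unachievable = function(e) e)
  expect_s3_class(err, "swd_unachievable")
  expect_lt(err$plateau, 0.999)
  expect_match(conditionMessage(err), "plateaus")
})

test_that("cluster solver searches equal allocations", {
  des <- swd_preset("sim_model1", clusters_per_sequence = 1,
                    n_per_cell = 50)
  sol <- swd_solve_clusters(des, target = 0.8)
  expect_equal(sol$total_clusters, sol$solution * 3L)
  expect_gte(sol$achieved, 0.8)
  lay1 <- des$layout
  lay1$clusters_per_sequence <- rep(sol$solution - 1L, 3L)
  expect_lt(swd_power(lay1, des$model)$power, 0.8)
})

test_that("power curves are deterministic and monotone", {
  des <- swd_preset("sim_model1", clusters_per_sequence = 4)
  one <- swd_power_curve(des, grid = des$layout$n_per_cell)
  expect_equal(nrow(one), 1L)
  expect_equal(one$power, swd_power(des$layout, des$model)$power)

  crv <- swd_power_curve(des, grid = c(20, 50, 100, 200, 300))
  expect_true(all(diff(crv$power) > 0))

  lire <- swd_preset("lire")
  for (npp in c(4, 6)) {
    lay <- lire$layout; lay$n_per_cell <- npp
    crv <- swd_power_curve(lay, lire$model,
                           variable = "clusters_per_sequence",
                           grid = seq(10, 45, by = 5))
    expect_true(all(diff(crv$power) > 0))
  }
})
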