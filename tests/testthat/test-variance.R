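test_that("working weights follow phi a v(mu) g'(mu)^2", {
  expect_equal(w0_weights("bernoulli", 0), 4)        # mu = 1/2
  fam <- swd_family("normal", dispersion = 2)
  expect_equal(w0_weights(fam, c(-1, 0, 3)), c(2, 2, 2))
  expect_equal(w0_weights("poisson", log(4)), 0.25)  # 1 * 1 * 4 * (1/4)^2
  expect_error(w0_weights("bernoulli", Inf), "non-finite")
})

test_that("cluster working covariance W + ZDZ' assembles correctly", {
  Z <- matrix(1, 2, 1)
  D <- matrix(0.25, 1, 1)
  V <- cluster_V(w0_weights("bernoulli", c(0, 0)), Z, D)
  expect_equal(V, rbind(c(4.25, 0.25), c(0.25, 4.25)))
  expect_equal(cluster_V(c(2, 3), Z, matrix(0, 1, 1)), diag(c(2, 3)))
  expect_equal(cluster_V(c(2, 3), matrix(0, 2, 1), matrix(5, 1, 1)),
               diag(c(2, 3)))
  expect_error(cluster_V(c(1, 1), matrix(1, 2, 2), D), "1:1")
})

test_that("woodbury inversion agrees with direct inversion", {
  # hand-checked 2x2
  w <- c(4.25, 4.25) - 0.25  # weights 4, plus random intercept var 0.25
  Vinv <- invert_V(c(4, 4), matrix(1, 2, 1), matrix(0.25, 1, 1),
                   method = "woodbury")
  expect_equal(unclass(Vinv), solve(rbind(c(4.25, 0.25), c(0.25, 4.25))),
               ignore_attr = TRUE, tolerance = 1e-12)
  # D = 0 collapses to the diagonal case
  Vinv0 <- invert_V(c(2, 5), matrix(1, 2, 1), matrix(0, 1, 1),
                    method = "woodbury")
  expect_equal(unclass(Vinv0), diag(1 / c(2, 5)), ignore_attr = TRUE)

  # randomized instances, including singular D
  set.seed(421)
  for (i in 1:25) {
    n <- sample(3:12, 1)
    q <- sample(1:4, 1)
    w <- exp(stats::rnorm(n))
    Z <- matrix(stats::rnorm(n * q), n, q)
    A <- matrix(stats::rnorm(q * q), q, q)
    D <- crossprod(A)
    if (i %% 3 == 0 && q > 1) {      # make D singular
      D[q, ] <- 0; D[, q] <- 0
    }
    direct <- invert_V(w, Z, D, method = "direct")
    wood <- invert_V(w, Z, D, method = "woodbury")
    expect_lt(rel_err(wood, direct), 1e-8)
  }
  expect_error(invert_V(c(1, 0), matrix(1, 2, 1), matrix(1, 1, 1)),
               "non-positive weight")
})

test_that("exchangeable-row aggregation preserves the information exactly", {
  lay <- swd_layout(1, 2, n_per_cell = 3)
  mod <- swd_model("bernoulli", prevalence = 0.3, time_effects = 0.1,
                   effect = 0.4, sd_cluster = 0.5)
  full <- build_cluster_block(lay, mod, 1, aggregate = FALSE)
  expect_equal(nrow(full$X), 6)
  red <- aggregate_cluster_block(full)
  expect_equal(nrow(red$X), 2)
  expect_equal(red$count, c(3L, 3L))

  w_full <- w0_weights(mod$family, linear_predictor(full, mod))
  w_red <- w0_weights(mod$family, linear_predictor(red, mod))
  info_full <- t(full$X) %*% invert_V(w_full, full$Z, full$D,
                                      "direct") %*% full$X
  info_red <- swdglmm:::block_information(red, w_red)
  expect_lt(rel_err(info_red, info_full), 1e-10)

  # n_per_cell = 1 leaves the block unchanged
  lay1 <- swd_layout(1, 2, n_per_cell = 1)
  b1 <- build_cluster_block(lay1, mod, 1, aggregate = FALSE)
  expect_equal(aggregate_cluster_block(b1)$count, c(1L, 1L))

  # two-level block: 840 individual rows reduce to 210 cells
  lire <- swd_preset("lire")
  fullL <- build_cluster_block(lire$layout, lire$model, 1,
                               aggregate = FALSE)
  expect_equal(nrow(fullL$X), 840)
  expect_equal(nrow(aggregate_cluster_block(fullL)$X), 210)
})

test_that("normal/identity covariance reproduces brute-force stacked GLS", {
  lay <- swd_layout(2, 3, clusters_per_sequence = 2, n_per_cell = 4)
  mod <- swd_model("normal", intercept = 1, time_effects = c(0.5, -0.2),
                   effect = 0.8, sd_cluster = 0.7, sd_treatment = 0.3,
                   dispersion = 2.5)
  v <- swd_variance(lay, mod)
  oracle <- gls_vcov_oracle(lay, mod)
  expect_lt(rel_err(v$vcov_alt, oracle), 1e-10)
  # exactness of the identity link: weights free of beta, so V0 = Va
  expect_identical(v$var_p_null, v$var_p_alt)
})

test_that("zero random effects recover the plain GLM information", {
  lay <- swd_layout(3, 4, clusters_per_sequence = 5, n_per_cell = 30)
  mod <- swd_model("bernoulli", prevalence = 0.12,
                   time_effects = c(0.1, 0.1, 0.1), effect = 0.2,
                   sd_cluster = 0, sd_treatment = 0)
  v <- swd_variance(lay, mod)
  expect_lt(rel_err(v$vcov_alt, solve(glm_info_oracle(lay, mod))), 1e-10)
})

test_that("variance responds to design size and scale as theory demands", {
  mod1 <- swd_model("normal", intercept = 0, time_effects = c(0, 0),
                    effect = 1, dispersion = 1, sd_cluster = 0)
  lay <- function(n, m) swd_layout(2, 3, clusters_per_sequence = m,
                                   n_per_cell = n)
  v1 <- swd_variance(lay(4, 2), mod1)$var_p_alt
  mod2 <- swd_model("normal", intercept = 0, time_effects = c(0, 0),
                    effect = 1, dispersion = 2, sd_cluster = 0)
  v2 <- swd_variance(lay(4, 2), mod2)$var_p_alt
  expect_equal(v2 / v1, 2, tolerance = 1e-12)

  modb <- swd_model("bernoulli", prevalence = 0.12,
                    time_effects = c(0.1, 0.1), effect = 0.2,
                    sd_cluster = 0.05, sd_treatment = 0.05)
  vn <- vapply(c(5, 10, 20, 40, 80),
               function(n) swd_variance(lay(n, 4), modb)$var_p_alt,
               numeric(1))
  expect_true(all(diff(vn) < 0))
  vm <- vapply(c(2, 4, 8, 16),
               function(m) swd_variance(lay(20, m), modb)$var_p_alt,
               numeric(1))
  expect_true(all(diff(vm) < 0))
})

test_that("inestimable designs raise a rank error", {
  # one sequence, two periods, categorical time: the period-2 dummy is
  # identical to the treatment column
  lay <- swd_layout(1, 2, clusters_per_sequence = 3, n_per_cell = 10)
  mod <- swd_model("bernoulli", prevalence = 0.3, time_effects = 0,
                   effect = 0.2, sd_cluster = 0.1)
  expect_error(swd_variance(lay, mod), "inestimable")
})
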