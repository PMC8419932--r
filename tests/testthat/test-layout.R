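test_that("standard schedule is the all-control-first staircase", {
  expect_equal(unname(standard_schedule(3, 4)),
               rbind(c(0, 1, 1, 1), c(0, 0, 1, 1), c(0, 0, 0, 1)))
  expect_equal(unname(standard_schedule(1, 2)), rbind(c(0, 1)))
  s45 <- standard_schedule(4, 5)
  for (s in 1:4) {
    expect_equal(unname(s45[s, ]), as.numeric(seq_len(5) > s))
  }
  expect_error(standard_schedule(3, 3), "invalid geometry")
})

test_that("schedule rows and columns behave like a staircase", {
  for (S in 1:5) {
    for (T_ in (S + 1):(S + 3)) {
      sched <- standard_schedule(S, T_)
      # row s has exactly T - s treated periods
      expect_equal(rowSums(sched), T_ - seq_len(S))
      # exposure only accumulates over time
      expect_true(all(diff(colSums(sched)) >= 0))
      expect_true(all(diff(colSums(sched))[seq_len(min(S, T_ - 1))] > 0))
    }
  }
})

test_that("layout expansion yields the full deterministic row table", {
  lay <- swd_layout(1, 2, n_per_cell = 3)
  rows <- expand_layout(lay)
  expect_length(rows, 1L)
  expect_equal(nrow(rows[[1]]), 6L)
  expect_equal(rows[[1]]$treatment, c(0, 0, 0, 1, 1, 1))
  expect_equal(rows[[1]]$period, rep(1:2, each = 3))

  lire <- swd_layout(5, 6, clusters_per_sequence = 1, subclusters = 35,
                     n_per_cell = 4)
  rows <- expand_layout(lire)
  expect_true(all(vapply(rows, nrow, integer(1)) == 6 * 35 * 4))

  ept <- swd_layout(4, 5, clusters_per_sequence = 2, n_per_cell = 7)
  rows <- expand_layout(ept)
  expect_true(all(vapply(rows, nrow, integer(1)) == 5 * 7))
  # clusters sharing a sequence are identical
  seqs <- vapply(rows, attr, integer(1), "sequence")
  for (s in unique(seqs)) {
    same <- rows[seqs == s]
    for (k in seq_along(same)) expect_identical(same[[k]], same[[1]],
                                                ignore_attr = TRUE)
  }
})

test_that("degenerate or custom schedules are validated", {
  expect_error(swd_layout(2, 3, schedule = matrix(0, 2, 3)), "inestimable")
  expect_error(swd_layout(2, 3, schedule = matrix(1, 2, 3)), "inestimable")
  wavy <- rbind(c(0, 1, 0), c(0, 0, 1))
  expect_error(swd_layout(2, 3, schedule = wavy), "non-decreasing")
  expect_silent(swd_layout(2, 3, schedule = wavy, custom = TRUE))
  expect_error(swd_layout(3, 4, clusters_per_sequence = c(2, 2)),
               "clusters_per_sequence")
  lay <- swd_layout(3, 4, clusters_per_sequence = c(4, 8, 12))
  expect_equal(sum(lay$clusters_per_sequence), 24L)
})
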