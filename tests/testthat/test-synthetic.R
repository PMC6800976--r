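test_that("state covariances have the requested block structure", {
  blocks <- rbind(c(1, 1, 2, 2), c(1, 2, 1, 2))
  spec <- synthetic_spec(n_regions = 4, n_timepoints = 100, n_states = 2,
                         r_in = 0.8, r_out = 0, blocks = blocks,
                         boundaries = 50, seed = 1)
  sig <- build_state_covariances(spec)
  expect_equal(sig[[1]],
               rbind(c(1, .8, 0, 0), c(.8, 1, 0, 0),
                     c(0, 0, 1, .8), c(0, 0, .8, 1)))
  expect_equal(sig[[2]][1, 3], 0.8)
  expect_equal(sig[[2]][1, 2], 0)
})

test_that("equal within- and between-block correlation collapses all states", {
  spec <- synthetic_spec(n_regions = 6, n_timepoints = 100, n_states = 3,
                         r_in = 0.3, r_out = 0.3, boundaries = c(33, 66),
                         seed = 1)
  sig <- build_state_covariances(spec)
  expect_equal(sig[[1]], sig[[2]])
  expect_equal(sig[[2]], sig[[3]])
  expect_equal(unique(sig[[1]][upper.tri(sig[[1]])]), 0.3)
})

test_that("state covariances are positive semi-definite (eigen oracle)", {
  spec <- synthetic_spec(n_regions = 6, n_timepoints = 100, n_states = 2,
                         r_in = 0.7, r_out = 0.1, boundaries = 50, seed = 1)
  for (sig in build_state_covariances(spec)) {
    expect_gt(min(eigen(sig, symmetric = TRUE, only.values = TRUE)$values), 0)
    expect_equal(diag(sig), rep(1, 6))
  }
})

test_that("an indefinite correlation request fails naming the state", {
  expect_error(
    synthetic_spec(n_regions = 6, n_timepoints = 100, n_states = 1,
                   r_in = 0, r_out = -0.9,
                   blocks = matrix(rep(1:2, each = 3), 1), seed = 1),
    "state 1"
  )
})

test_that("sharp boundaries give empty ramps and exact label switches", {
  spec <- scaled_spec(n_states = 3, ramp = 0, jitter = 0, seed = 3)
  sim <- generate_bold(spec)
  tr <- sim$truth[[1]]
  expect_length(tr$ramps, 0)
  expect_equal(tr$boundaries, spec$boundaries)
  b <- tr$boundaries
  expect_equal(tr$labels[b[1]], 1L)
  expect_equal(tr$labels[b[1] + 1L], 2L)
  expect_equal(tr$labels[b[2]], 2L)
  expect_equal(tr$labels[b[2] + 1L], 3L)
  expect_equal(sort(unique(tr$labels)), 1:3)
})

test_that("ramp intervals are recorded, disjoint, and contain their boundary", {
  spec <- scaled_spec(n_states = 3, ramp = 11, jitter = 5, n_subjects = 4,
                      seed = 9)
  sim <- generate_bold(spec)
  for (tr in sim$truth) {
    expect_length(tr$ramps, 2)
    ends <- t(vapply(tr$ramps, identity, numeric(2)))
    expect_true(all(ends[, 1] <= tr$boundaries & tr$boundaries <= ends[, 2]))
    expect_lt(ends[1, 2], ends[2, 1])  # pairwise disjoint
    expect_true(all(ends >= 1 & ends <= spec$n_timepoints))
  }
})

test_that("per-subject jitter stays within bounds and keeps boundary order", {
  spec <- scaled_spec(n_states = 3, jitter = 15, n_subjects = 10, seed = 4)
  sim <- generate_bold(spec)
  for (tr in sim$truth) {
    expect_true(all(abs(tr$boundaries - spec$boundaries) <= 15))
    expect_true(all(diff(tr$boundaries) > 0))
  }
})

test_that("generation is a pure function of the spec", {
  spec <- scaled_spec(n_states = 3, ramp = 7, jitter = 4, n_subjects = 2,
                      seed = 11)
  a <- generate_bold(spec)
  b <- generate_bold(spec)
  expect_identical(a$subjects[[1]]$values, b$subjects[[1]]$values)
  expect_identical(a$subjects[[2]]$values, b$subjects[[2]]$values)
  expect_identical(a$truth, b$truth)
})

test_that("long steady segments reproduce the target correlations", {
  spec <- synthetic_spec(n_regions = 6, n_timepoints = 2000, n_states = 1,
                         r_in = 0.8, r_out = 0.1, n_subjects = 1, seed = 5)
  sim <- generate_bold(spec)
  emp <- cor(sim$subjects[[1]]$values)
  same <- outer(spec$blocks[1, ], spec$blocks[1, ], `==`)
  within <- emp[same & upper.tri(emp)]
  between <- emp[!same & upper.tri(emp)]
  expect_true(all(within > 0.75 & within < 0.85))
  expect_true(all(abs(between - 0.1) < 0.08))
})
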