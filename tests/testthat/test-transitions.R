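# A tiny observation matrix with three clearly separated regimes, cheap
# enough for repeated embedding in unit tests.
tiny_G <- function(seed = 1) {
  sim <- generate_bold(synthetic_spec(n_regions = 10, n_timepoints = 120,
                                      n_states = 3, seed = seed))
  build_connectivity_sequence(sim$subjects[[1]])$G
}

test_that("repeated runs conserve histogram mass and count failures", {
  G <- tiny_G()
  cfg <- embedding_config(perplexity = 20, n_iterations = 300)
  h1 <- repeat_runs(G, m = 3, reps = 1, base_seed = 5, embedding = cfg)
  expect_s3_class(h1, "cp_histogram")
  if (h1$reps_successful == 1) {
    expect_true(all(rowSums(h1$counts) == 1))
    expect_true(all(apply(h1$counts, 1, max) == 1))  # one-hot rows
  }
  h <- repeat_runs(G, m = 3, reps = 8, base_seed = 1, embedding = cfg)
  expect_equal(unname(rowSums(h$counts)), rep(h$reps_successful, 2))
  expect_true(all(h$counts >= 0))
  expect_lte(h$reps_successful, h$reps_attempted)
})

test_that("interval estimation matches the brute-force enumerator", {
  g <- 30
  one_spike <- replace(numeric(g), 42 %% g, 12)  # all mass at one window
  iv <- estimate_interval(one_spike, alpha = 0.9)
  expect_equal(c(iv$t1, iv$t2), rep(which(one_spike > 0), 2))

  unif <- c(rep(1, 10), numeric(20))
  iv2 <- estimate_interval(unif, alpha = 0.9)
  expect_equal(c(iv2$t1, iv2$t2), c(1, 9))

  spikes <- numeric(g); spikes[c(10, 20)] <- 5
  iv3 <- estimate_interval(spikes, alpha = 0.9)
  expect_equal(c(iv3$t1, iv3$t2), oracle_shortest_interval(spikes, 0.9))
  expect_equal(c(iv3$t1, iv3$t2), c(10, 20))

  set.seed(31)
  for (i in 1:25) {
    counts <- rpois(25, lambda = 1.5)
    if (sum(counts) == 0) counts[7] <- 1
    alpha <- sample(c(0.5, 0.8, 0.9, 1), 1)
    iv <- estimate_interval(counts, alpha = alpha)
    expect_equal(c(iv$t1, iv$t2), oracle_shortest_interval(counts, alpha))
  }
  expect_error(estimate_interval(numeric(10)), "no mass")
})

test_that("interval overlap counts shared inclusive indices", {
  expect_equal(interval_overlap(c(1, 5), c(10, 12)), 0L)
  expect_equal(interval_overlap(c(5, 10), c(5, 10)), 6L)
  expect_equal(interval_overlap(c(5, 10), c(8, 12)), 3L)
  set.seed(8)
  for (i in 1:30) {
    a <- sort(sample(1:50, 2)); b <- sort(sample(1:50, 2))
    expect_equal(interval_overlap(a, b), oracle_interval_overlap(a, b))
    expect_equal(interval_overlap(a, b), interval_overlap(b, a))
  }
})

test_that("coincidence degree averages normalized adjacent overlaps", {
  iv <- function(t1, t2) structure(list(q = 1L, t1 = t1, t2 = t2,
                                        alpha = 0.9, mass = 1),
                                   class = "transition_interval")
  disjoint <- list(list(iv(5, 10), iv(30, 40), iv(60, 70)))
  expect_equal(coincidence_degree(disjoint, 157)$Q_bar, 0)

  one <- list(list(iv(5, 10), iv(8, 12)))
  expect_equal(coincidence_degree(one, 157)$Q, 3 / 157)

  two <- list(list(iv(5, 10), iv(8, 12)), list(iv(5, 10), iv(8, 12)))
  co <- coincidence_degree(two, 157)
  expect_equal(co$Q_bar, 3 / 157)

  shuffled <- coincidence_degree(rev(two), 157)
  expect_equal(shuffled$Q_bar, co$Q_bar)
})

test_that("conversion curves rise monotonically to one", {
  iv <- function(t1, t2) structure(list(q = 1L, t1 = t1, t2 = t2,
                                        alpha = 0.9, mass = 1),
                                   class = "transition_interval")
  g <- 40
  front <- replace(numeric(g), 12, 9)
  lam <- conversion_rate(front, iv(12, 20))
  expect_true(all(lam$lambda == 1))  # all mass already at t1

  unif <- replace(numeric(g), 11:20, 2)
  lam2 <- conversion_rate(unif, iv(11, 20))
  expect_equal(lam2$lambda, seq(0.1, 1, by = 0.1))

  set.seed(14)
  for (i in 1:20) {
    counts <- rpois(g, 1); counts[15] <- counts[15] + 1
    cur <- conversion_rate(counts, iv(10, 25))
    expect_true(all(diff(cur$lambda) >= 0))
    expect_equal(cur$lambda[length(cur$lambda)], 1)
    scaled <- conversion_rate(counts * 7, iv(10, 25))
    expect_equal(scaled$lambda, cur$lambda)
  }

  dens <- conversion_rate(unif, iv(11, 20), form = "density")
  expect_equal(dens$lambda * 10, lam2$lambda)
  expect_error(conversion_rate(numeric(g), iv(3, 5)), "no mass")
})
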