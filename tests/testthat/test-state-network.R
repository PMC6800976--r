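iv <- function(q, t1, t2) structure(list(q = q, t1 = t1, t2 = t2,
                                         alpha = 0.9, mass = 1),
                                    class = "transition_interval")

test_that("the partition alternates steady and transition sets exactly", {
  p <- build_partition(list(iv(1, 10, 15), iv(2, 51, 55),
                            iv(3, 86, 90), iv(4, 126, 130)), 157, 5)
  expect_equal(p$s, 9L)
  expect_equal(p$kind, rep(c("steady", "transition"), length.out = 9))
  all_idx <- sort(unlist(p$sets))
  expect_equal(all_idx, 1:157)           # covers every window exactly once
  expect_equal(anyDuplicated(unlist(p$sets)), 0L)

  p2 <- build_partition(list(iv(1, 10, 15)), 30, 2)
  expect_equal(p2$sets, list(1:9, 10:15, 16:30))

  expect_error(build_partition(list(iv(1, 10, 15), iv(2, 16, 20)), 30, 3),
               "empty steady gap")
  expect_error(build_partition(list(iv(1, 25, 30)), 30, 2), "after the last")
})

test_that("the reference 9-interval layout reproduces the fixed state sets", {
  p <- partition_hc9()
  expect_equal(p$s, 9L)
  expect_equal(p$sets[[1]], 1:9)     # boundary window 10 goes to transition
  expect_equal(p$sets[[2]], 10:15)
  expect_equal(p$sets[[4]], 51:55)
  expect_equal(p$sets[[6]], 86:90)
  expect_equal(p$sets[[8]], 126:130)
  expect_equal(p$sets[[9]], 131:157)
  expect_error(partition_hc9(120), "157")
})

test_that("state averaging is the element-wise mean of window networks", {
  sim <- generate_bold(synthetic_spec(n_regions = 6, n_timepoints = 80,
                                      n_states = 1, seed = 3))
  conn <- build_connectivity_sequence(sim$subjects[[1]])
  expect_equal(average_state_matrix(conn, 5), conn$matrices[[5]])
  expect_equal(average_state_matrix(conn, c(2, 9)),
               (conn$matrices[[2]] + conn$matrices[[9]]) / 2)
  expect_error(average_state_matrix(conn, integer(0)), "empty")

  a <- matrix(0, 4, 4); a[1, 2] <- a[2, 1] <- 1
  b <- matrix(0, 4, 4)
  fake <- structure(list(n_windows = 2L, matrices = list(a, b)),
                    class = "connectivity_sequence")
  expect_equal(average_state_matrix(fake, 1:2)[1, 2], 0.5)
})

test_that("group state networks average subjects element-wise", {
  s1 <- list(matrix(0.2, 3, 3), matrix(0.4, 3, 3))
  s2 <- list(matrix(0.6, 3, 3), matrix(0.8, 3, 3))
  g <- group_state_networks(list(s1, s2))
  expect_equal(g[[1]], matrix(0.4, 3, 3))
  expect_equal(g[[2]], matrix(0.6, 3, 3))
  expect_equal(group_state_networks(list(s1))[[1]], s1[[1]])
  expect_true(all(vapply(g, function(m) all(m >= 0 & m <= 1), logical(1))))
  expect_error(group_state_networks(list(s1, list(matrix(0, 2, 2), matrix(0, 2, 2)))),
               "inconsistent")
})

test_that("node overlap matches term-by-term evaluation and its bounds", {
  ring <- matrix(0, 5, 5)
  for (i in 1:5) { j <- i %% 5 + 1; ring[i, j] <- ring[j, i] <- 1 }
  for (mode in c("default", "classic")) {
    expect_equal(node_overlap(ring, ring, 1, mode), 1)
    expect_equal(network_overlap(ring, ring, mode), 1)
  }

  a <- matrix(0, 4, 4); a[1, 2] <- a[2, 1] <- 1
  b <- matrix(0, 4, 4); b[1, 3] <- b[3, 1] <- 1
  expect_equal(node_overlap(a, b, 1), 0)  # disjoint neighborhoods

  za <- matrix(0, 3, 3); za[1, 2] <- za[2, 1] <- 0.8; za[1, 3] <- za[3, 1] <- 0.4
  zb <- matrix(0, 3, 3); zb[1, 2] <- zb[2, 1] <- 0.6; zb[1, 3] <- zb[3, 1] <- 0.4
  for (mode in c("default", "classic")) {
    expect_equal(node_overlap(za, zb, 1, mode),
                 oracle_node_overlap(za, zb, 1, mode), tolerance = 1e-12)
  }

  set.seed(17)
  for (i in 1:20) {
    x <- random_weighted_adjacency(6)
    y <- random_weighted_adjacency(6)
    ci <- vapply(1:6, function(k) node_overlap(x, y, k), numeric(1))
    expect_true(all(ci >= 0 & ci <= 1 + 1e-12))
    expect_equal(network_overlap(x, y), network_overlap(y, x))
    expect_equal(network_overlap(x, y), mean(ci))
  }
  expect_error(network_overlap(za * 3, zb), "\\[0, 1\\]")
})

test_that("the overlap matrix is symmetric with a zero diagonal", {
  set.seed(23)
  nets <- replicate(9, random_weighted_adjacency(8), simplify = FALSE)
  nets[[5]] <- nets[[1]]  # one identical pair
  om <- overlap_matrix(nets)
  expect_equal(dim(om), c(9L, 9L))
  expect_equal(unclass(om), t(unclass(om)), ignore_attr = TRUE)
  expect_equal(diag(om), setNames(rep(0, 9), paste0("S", 1:9)))
  off <- overlap_values(om)
  expect_length(off, 36)
  expect_equal(max(off), om[1, 5])  # identical networks are most similar
})
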