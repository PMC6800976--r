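# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive loops and textbook formulas, never the
# package's own code paths.

# Pearson correlation matrix straight from the textbook formula.
oracle_pearson <- function(x) {
  n <- ncol(x)
  r <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      xi <- x[, i] - mean(x[, i])
      xj <- x[, j] - mean(x[, j])
      r[i, j] <- r[j, i] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    }
  }
  r
}

# Row-major upper-triangle extraction by explicit double loop.
oracle_vectorize <- function(a) {
  n <- nrow(a)
  out <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) out <- c(out, a[i, j])
  }
  out
}

# Shortest contiguous interval holding >= alpha of the total mass,
# enumerating every (t1, t2) pair; ties resolved by length then t1.
oracle_shortest_interval <- function(counts, alpha) {
  g <- length(counts)
  need <- alpha * sum(counts)
  best <- NULL
  for (t1 in seq_len(g)) {
    for (t2 in t1:g) {
      if (sum(counts[t1:t2]) >= need - 1e-12) {
        len <- t2 - t1 + 1
        if (is.null(best) || len < best[3] ||
            (len == best[3] && t1 < best[1])) {
          best <- c(t1, t2, len)
        }
        break  # longer t2 with same t1 cannot be shorter
      }
    }
  }
  best[1:2]
}

# Inclusive integer interval overlap by enumeration of shared indices.
oracle_interval_overlap <- function(a, b) {
  length(intersect(seq(a[1], a[2]), seq(b[1], b[2])))
}

# Per-node topology overlap, term by term.
oracle_node_overlap <- function(za, zb, i, mode = "default") {
  num <- 0
  sa <- 0
  sb <- 0
  for (j in seq_len(ncol(za))) {
    w <- if (mode == "default") 1 - abs(za[i, j] - zb[i, j]) else 1
    num <- num + w * za[i, j] * zb[i, j]
    sa <- sa + za[i, j]
    sb <- sb + zb[i, j]
  }
  if (sa == 0 || sb == 0) return(0)
  num / sqrt(sa * sb)
}

# One-way ANOVA from the defining sums of squares.
oracle_anova <- function(a, b) {
  y <- c(a, b)
  gm <- mean(y)
  ssb <- length(a) * (mean(a) - gm)^2 + length(b) * (mean(b) - gm)^2
  ssw <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  dfb <- 1
  dfw <- length(y) - 2
  f <- (ssb / dfb) / (ssw / dfw)
  list(ssb = ssb, ssw = ssw, f = f, p = stats::pf(f, dfb, dfw, lower.tail = FALSE))
}

# Mean silhouette width of a labeling on 2-D points (euclidean).
silhouette_score <- function(coords, labels) {
  d <- as.matrix(stats::dist(coords))
  n <- nrow(coords)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(x, y) {
  tab <- table(x, y)
  comb2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- comb2(as.vector(tab))
  sum_i <- comb2(rowSums(tab))
  sum_j <- comb2(colSums(tab))
  n2 <- comb2(sum(tab))
  expected <- sum_i * sum_j / n2
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}

# Small random symmetric matrix with zero diagonal and entries in [0, 1].
random_weighted_adjacency <- function(n) {
  a <- matrix(stats::runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  a
}

# Scaled synthetic cohort used by several suites: N regions, T time points,
# latent states with optional ramps/jitter.
scaled_spec <- function(n_states = 3, ramp = 0, jitter = 0, n_subjects = 1,
                        seed = 1) {
  synthetic_spec(n_regions = 20, n_timepoints = 200, n_states = n_states,
                 r_in = 0.7, r_out = 0.1, ramp_length = ramp,
                 boundary_jitter = jitter, n_subjects = n_subjects,
                 seed = seed)
}
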