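#' Specification of a synthetic multi-subject BOLD cohort
#'
#' Describes a piecewise-stationary multivariate Gaussian process whose
#' correlation structure switches between `n_states` latent connectivity
#' regimes. Each regime is a block covariance: unit variances, correlation
#' `r_in` within a block of regions and `r_out` across blocks; the block
#' membership rotates from state to state (or is supplied explicitly), so
#' consecutive states differ in many region pairs. State boundaries are
#' evenly spaced by default; each boundary may be crossed gradually over a
#' ramp of `ramp_length` time points during which the covariance is the
#' convex mixture (1 - w) * Sigma_p + w * Sigma_{p+1} with w increasing
#' linearly, and each subject's boundaries are shifted by an integer drawn
#' uniformly from \[-boundary_jitter, boundary_jitter\].
#'
#' All state covariances are validated to be positive semi-definite at
#' construction, and the scheduled boundaries plus ramps must fit strictly
#' inside the recording. Jittered boundaries are clamped per subject so they
#' stay strictly increasing, and ramps are truncated at the midpoints between
#' neighboring boundaries so ramp intervals remain pairwise disjoint — under
#' heavy jitter adjacent transitions may therefore crowd each other, which is
#' the intended irregular-dynamics regime.
#'
#' The defaults mirror a resting-state acquisition: 90 regions, 176 time
#' points, 5 connectivity states with evenly spaced boundaries, and 20
#' subjects per cohort.
#'
#' @param n_regions Number of regions N (>= 3).
#' @param n_timepoints Recording length T.
#' @param n_states Number of latent states m_true.
#' @param r_in Within-block correlation in \[0, 1).
#' @param r_out Between-block correlation, `r_out < r_in`.
#' @param ramp_length Time points of gradual covariance mixing at each
#'   boundary; 0 = instantaneous switch.
#' @param boundary_jitter Maximum per-subject shift of each boundary.
#' @param n_subjects Number of subjects to simulate.
#' @param boundaries Optional increasing vector of m_true - 1 scheduled
#'   boundary time points (the last time point of each state); defaults to
#'   even spacing `round(p * T / m_true)`.
#' @param blocks Optional n_states x n_regions integer matrix of block ids
#'   (row p = state p's block assignment). By default states share a common
#'   balanced two-block backbone and consecutive states relocate
#'   `state_shift` regions between blocks, so state networks are variations
#'   on a shared connectome rather than unrelated topologies.
#' @param n_blocks Number of blocks for the default assignment (default 2).
#' @param state_shift Regions relocated between consecutive states in the
#'   default assignment (default ~10 percent of regions).
#' @param seed Integer seed; the generated cohort is a pure function of the
#'   spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_regions = 90L, n_timepoints = 176L, n_states = 5L,
                           r_in = 0.7, r_out = 0.1, ramp_length = 0L,
                           boundary_jitter = 0L, n_subjects = 20L,
                           boundaries = NULL, blocks = NULL, n_blocks = 2L,
                           state_shift = NULL, seed = 1L) {
  n_regions <- as.integer(n_regions)
  n_timepoints <- as.integer(n_timepoints)
  n_states <- as.integer(n_states)
  ramp_length <- as.integer(ramp_length)
  boundary_jitter <- as.integer(boundary_jitter)
  n_subjects <- as.integer(n_subjects)
  if (n_regions < 3L) stop("synthetic_spec: need at least 3 regions", call. = FALSE)
  if (n_states < 1L) stop("synthetic_spec: need at least one state", call. = FALSE)
  if (!(r_in >= 0 && r_in < 1) || !(r_out < 1)) {
    stop("synthetic_spec: correlations must lie in [0, 1)", call. = FALSE)
  }
  if (n_states > 1L && r_out > r_in) {
    stop("synthetic_spec: r_out must not exceed r_in", call. = FALSE)
  }
  if (ramp_length < 0L || boundary_jitter < 0L || n_subjects < 1L) {
    stop("synthetic_spec: counts must be non-negative", call. = FALSE)
  }

  if (is.null(boundaries)) {
    boundaries <- if (n_states > 1L) {
      as.integer(round(seq_len(n_states - 1L) * n_timepoints / n_states))
    } else integer(0)
  }
  boundaries <- as.integer(boundaries)
  if (length(boundaries) != n_states - 1L) {
    stop("synthetic_spec: need n_states - 1 boundaries", call. = FALSE)
  }
  # scheduled boundaries strictly increasing, ramps inside the recording
  half <- ceiling(ramp_length / 2)
  if (length(boundaries) > 0L &&
      (is.unsorted(boundaries, strictly = TRUE) ||
       any(boundaries - half < 1L) ||
       any(boundaries + half >= n_timepoints))) {
    stop("synthetic_spec: boundaries with ramps do not fit inside the recording",
         call. = FALSE)
  }

  if (is.null(blocks)) {
    n_blocks <- as.integer(n_blocks)
    if (is.null(state_shift)) state_shift <- max(1L, n_regions %/% 10L)
    shift <- as.integer(state_shift)
    base <- rep(seq_len(n_blocks), each = ceiling(n_regions / n_blocks))[seq_len(n_regions)]
    blocks <- t(vapply(seq_len(n_states), function(p) {
      idx <- ((seq_len(n_regions) - 1L + (p - 1L) * shift) %% n_regions) + 1L
      base[idx]
    }, integer(n_regions)))
  }
  blocks <- matrix(as.integer(blocks), nrow = n_states)
  if (ncol(blocks) != n_regions) {
    stop("synthetic_spec: blocks must have one column per region", call. = FALSE)
  }

  spec <- structure(
    list(n_regions = n_regions, n_timepoints = n_timepoints,
         n_states = n_states, r_in = r_in, r_out = r_out,
         ramp_length = ramp_length, boundary_jitter = boundary_jitter,
         n_subjects = n_subjects, boundaries = boundaries, blocks = blocks,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
  build_state_covariances(spec)  # validates PSD at construction
  spec
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec> %d subjects, %d x %d, %d states, r_in = %g, r_out = %g, ramp = %d, jitter = %d, seed = %d\n",
              x$n_subjects, x$n_timepoints, x$n_regions, x$n_states,
              x$r_in, x$r_out, x$ramp_length, x$boundary_jitter, x$seed))
  invisible(x)
}

#' Per-state block covariance matrices
#'
#' One N x N covariance per latent state: unit diagonal, `r_in` for region
#' pairs in the same block, `r_out` across blocks. Each matrix is checked
#' for positive semi-definiteness; a failure names the offending state.
#'
#' @param spec A [synthetic_spec].
#' @return List of `n_states` symmetric PSD matrices.
#' @export
build_state_covariances <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec") || is.list(spec))
  lapply(seq_len(spec$n_states), function(p) {
    b <- spec$blocks[p, ]
    same <- outer(b, b, `==`)
    sigma <- ifelse(same, spec$r_in, spec$r_out)
    diag(sigma) <- 1
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stop(sprintf("build_state_covariances: state %d covariance is not positive semi-definite (min eigenvalue %.3g)",
                   p, min(ev)), call. = FALSE)
    }
    sigma
  })
}

# Clamp per-subject jittered boundaries so they stay strictly increasing
# and strictly inside (1, T).
clamp_boundaries <- function(b, t_len) {
  k <- length(b)
  if (k == 0L) return(b)
  for (q in seq_len(k)) {
    b[q] <- max(b[q], if (q > 1L) b[q - 1L] + 1L else 1L)
  }
  for (q in rev(seq_len(k))) {
    b[q] <- min(b[q], if (q < k) b[q + 1L] - 1L else t_len - 1L)
  }
  b
}

# Per-time-point mixing weight of the NEXT state: 0 outside ramps, rising
# linearly strictly inside a ramp centered on each (jittered) boundary, and
# a step at the boundary when ramp_length = 0. Ramps are truncated at the
# midpoints between neighboring boundaries (and at the recording edges) so
# ramp intervals stay pairwise disjoint even when jitter crowds boundaries.
state_mixture_schedule <- function(spec, boundaries) {
  t_len <- spec$n_timepoints
  m <- spec$n_states
  state <- rep.int(m, t_len)
  if (m > 1L) {
    state <- findInterval(seq_len(t_len) - 1L, boundaries) + 1L
  }
  w_next <- numeric(t_len)
  ramps <- list()
  rho <- spec$ramp_length
  if (rho > 0L) {
    k <- length(boundaries)
    for (q in seq_len(k)) {
      b <- boundaries[q]
      lo <- max(b - ceiling(rho / 2) + 1L,
                if (q > 1L) (boundaries[q - 1L] + b) %/% 2L + 1L else 1L)
      hi <- min(b + rho %/% 2L,
                if (q < k) (b + boundaries[q + 1L]) %/% 2L else t_len - 1L)
      idx <- lo:hi
      len <- length(idx)
      w <- seq_len(len) / (len + 1)
      # points past the boundary already belong to state q+1: their mixture
      # weight refers to the PREVIOUS state, encode via state vector + w_next
      w_next[idx] <- ifelse(idx <= b, w, w - 1)  # negative => blend backwards
      ramps[[q]] <- c(idx[1L], idx[length(idx)])
    }
  }
  list(state = state, w_next = w_next, ramps = ramps)
}

#' Generate a synthetic BOLD cohort with ground truth
#'
#' Draws every subject's T x N series from the piecewise-stationary Gaussian
#' model described by the spec: inside a steady segment of state p, samples
#' are N(0, Sigma_p); inside a ramp the covariance is the convex mixture of
#' the two adjacent states with a linearly increasing weight. Boundaries are
#' jittered independently per subject. Identical specs (including seed)
#' produce bit-identical cohorts.
#'
#' @param spec A [synthetic_spec].
#' @return List with `subjects` (list of [region_ts]) and `truth`, a list
#'   per subject holding `labels` (true state per time point, switching
#'   after the jittered boundary), `boundaries`, and `ramps` (list of
#'   `c(start, end)` time-point pairs; empty when `ramp_length = 0`).
#' @export
generate_bold <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  sigmas <- build_state_covariances(spec)
  chols <- lapply(sigmas, chol)
  n <- spec$n_regions
  t_len <- spec$n_timepoints
  labels_regions <- sprintf("R%02d", seq_len(n))

  set.seed(spec$seed)
  subjects <- vector("list", spec$n_subjects)
  truth <- vector("list", spec$n_subjects)
  for (y in seq_len(spec$n_subjects)) {
    # jitter offsets are drawn unconditionally (scaled uniforms) so cohorts
    # generated from the same seed share all random draws and differ only in
    # their jitter/ramp settings — a paired design for group contrasts
    u <- stats::runif(length(spec$boundaries))
    jit <- as.integer(round((2 * u - 1) * spec$boundary_jitter))
    b_sub <- clamp_boundaries(spec$boundaries + jit, t_len)
    sched <- state_mixture_schedule(spec, b_sub)

    x <- matrix(NA_real_, t_len, n)
    z <- matrix(stats::rnorm(t_len * n), t_len, n)
    # cache mixture Cholesky factors per (state, weight) to avoid refactoring
    cache <- new.env(parent = emptyenv())
    for (t in seq_len(t_len)) {
      p <- sched$state[t]
      w <- sched$w_next[t]
      R <- if (w == 0) {
        chols[[p]]
      } else {
        key <- sprintf("%d|%.12f", p, w)
        if (is.null(cache[[key]])) {
          sig <- if (w > 0) (1 - w) * sigmas[[p]] + w * sigmas[[p + 1L]]
                 else (-w) * sigmas[[p - 1L]] + (1 + w) * sigmas[[p]]
          cache[[key]] <- chol(sig)
        }
        cache[[key]]
      }
      x[t, ] <- z[t, ] %*% R
    }
    subjects[[y]] <- region_ts(x, labels_regions)
    truth[[y]] <- list(labels = sched$state, boundaries = b_sub,
                       ramps = sched$ramps)
  }
  list(subjects = subjects, truth = truth, spec = spec)
}
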