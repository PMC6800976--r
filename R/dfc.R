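#' Region-level BOLD time series
#'
#' Container for a single subject's parcellated BOLD recording: a numeric
#' matrix with one row per sampling time point and one column per brain
#' region (e.g. 176 time points by 90 AAL regions), plus region labels and
#' the repetition time as metadata.
#'
#' @param values Numeric T x N matrix, rows = time points, columns = regions.
#' @param region_labels Character vector of N region names; defaults to the
#'   column names of `values`, or `R1..RN` when absent.
#' @param tr_seconds Repetition time in seconds (metadata only).
#' @return An object of class `region_ts`.
#' @export
region_ts <- function(values, region_labels = NULL, tr_seconds = 2) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) {
    stop("region_ts: all values must be finite", call. = FALSE)
  }
  if (ncol(values) < 3L) stop("region_ts: need at least 3 regions", call. = FALSE)
  if (nrow(values) < 2L) stop("region_ts: need at least 2 time points", call. = FALSE)
  if (is.null(region_labels)) {
    region_labels <- colnames(values)
    if (is.null(region_labels)) region_labels <- paste0("R", seq_len(ncol(values)))
  }
  if (length(region_labels) != ncol(values)) {
    stop("region_ts: region_labels length must match column count", call. = FALSE)
  }
  if (!is.numeric(tr_seconds) || tr_seconds <= 0) {
    stop("region_ts: tr_seconds must be positive", call. = FALSE)
  }
  colnames(values) <- region_labels
  structure(
    list(values = values, region_labels = region_labels,
         tr_seconds = tr_seconds),
    class = "region_ts"
  )
}

#' @export
print.region_ts <- function(x, ...) {
  cat(sprintf("<region_ts> %d time points x %d regions (TR = %g s)\n",
              nrow(x$values), ncol(x$values), x$tr_seconds))
  invisible(x)
}

#' Sliding-window configuration
#'
#' Parameters of the dynamic functional connectivity construction: window
#' length `n`, step `l`, the absolute-correlation threshold, the edge-weight
#' mode, and which matrices feed the vectorized feature rows.
#'
#' @param window Window length in time points (default 20).
#' @param step Window step in time points (default 1).
#' @param threshold Threshold applied to absolute Pearson correlations,
#'   in \[0, 1\] (default 0.5). Edges with |r| below it are removed; |r| equal
#'   to the threshold is retained.
#' @param mode `"weighted_abs"` keeps |r| as the edge weight (default);
#'   `"binary"` records edge presence as 0/1.
#' @param features `"thresholded"` (default) vectorizes the thresholded
#'   adjacency matrices; `"raw"` vectorizes the unthresholded |r| matrices.
#' @return An object of class `window_config`.
#' @export
window_config <- function(window = 20L, step = 1L, threshold = 0.5,
                          mode = c("weighted_abs", "binary"),
                          features = c("thresholded", "raw")) {
  mode <- match.arg(mode)
  features <- match.arg(features)
  window <- as.integer(window); step <- as.integer(step)
  if (step < 1L || window < step) {
    stop("window_config: need 1 <= step <= window", call. = FALSE)
  }
  if (threshold < 0 || threshold > 1) {
    stop("window_config: threshold must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(window = window, step = step, threshold = threshold,
         mode = mode, features = features),
    class = "window_config"
  )
}

#' Number of sliding windows
#'
#' Closed form for the number of windows of length `n` advanced in steps of
#' `l` over `T` time points: `floor((T - n) / l) + 1`. For step 1 this is
#' `T - n + 1` (e.g. 176 time points with a 20-point window give 157 windows).
#'
#' @param n_timepoints Total number of time points T.
#' @param window Window length n.
#' @param step Step l.
#' @return Integer window count g.
#' @export
count_windows <- function(n_timepoints, window, step = 1L) {
  n_timepoints <- as.integer(n_timepoints)
  window <- as.integer(window); step <- as.integer(step)
  if (step < 1L || window < step) stop("count_windows: need 1 <= step <= window",
                                       call. = FALSE)
  if (window > n_timepoints) stop("count_windows: window exceeds series length",
                                  call. = FALSE)
  as.integer((n_timepoints - window) %/% step + 1L)
}

#' Pearson correlation matrix of one window
#'
#' Pairwise Pearson correlations between all regions over the `n` in-window
#' samples starting at 1-based time point `start`. Regions with zero variance
#' inside the window get correlation 0 with every other region (diagonal
#' stays 1) and a warning names them.
#'
#' @param ts A [region_ts].
#' @param start 1-based index of the first in-window time point.
#' @param window Window length n (>= 3).
#' @return Symmetric N x N correlation matrix with unit diagonal.
#' @export
window_correlation <- function(ts, start, window) {
  stopifnot(inherits(ts, "region_ts"))
  start <- as.integer(start); window <- as.integer(window)
  if (window < 3L) stop("window_correlation: window must be >= 3", call. = FALSE)
  if (start < 1L || start + window - 1L > nrow(ts$values)) {
    stop("window_correlation: window out of bounds", call. = FALSE)
  }
  x <- ts$values[start:(start + window - 1L), , drop = FALSE]
  sds <- apply(x, 2L, stats::sd)
  flat <- sds == 0
  r <- suppressWarnings(stats::cor(x))
  if (any(flat)) {
    warning(sprintf("window starting at %d: zero-variance region(s) %s; correlations set to 0",
                    start, paste(ts$region_labels[flat], collapse = ", ")),
            call. = FALSE)
    r[flat, ] <- 0
    r[, flat] <- 0
  }
  diag(r) <- 1
  dimnames(r) <- list(ts$region_labels, ts$region_labels)
  r
}

#' Threshold a correlation matrix into an adjacency matrix
#'
#' Takes absolute values, removes entries below the threshold, and zeroes the
#' diagonal. Entries exactly at the threshold are kept.
#'
#' @param r Correlation matrix with entries in \[-1, 1\].
#' @param threshold Threshold in \[0, 1\].
#' @param mode `"weighted_abs"` keeps |r| as the weight; `"binary"` sets
#'   surviving edges to 1.
#' @return Adjacency matrix of the same dimension, zero diagonal.
#' @export
apply_threshold <- function(r, threshold = 0.5,
                            mode = c("weighted_abs", "binary")) {
  mode <- match.arg(mode)
  r <- as.matrix(r)
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    stop("apply_threshold: entries must lie in [-1, 1]", call. = FALSE)
  }
  a <- abs(r)
  a[a < threshold] <- 0
  if (mode == "binary") a[a > 0] <- 1
  diag(a) <- 0
  a
}

#' Vectorize the upper triangle of a symmetric matrix
#'
#' Extracts the strictly-upper-triangular entries in row-major order
#' ((1,2), (1,3), ..., (1,N), (2,3), ...), giving a vector of length
#' d = N(N-1)/2; 90 regions yield 4005 components.
#'
#' @param a Symmetric N x N matrix.
#' @return Numeric vector of length N(N-1)/2.
#' @seealso [devectorize()]
#' @export
vectorize_upper <- function(a) {
  a <- as.matrix(a)
  if (nrow(a) != ncol(a)) stop("vectorize_upper: matrix must be square", call. = FALSE)
  ta <- t(a)
  ta[lower.tri(ta)]
}

#' Rebuild a symmetric matrix from its upper-triangle vector
#'
#' Inverse of [vectorize_upper()]: places the d = N(N-1)/2 entries back in
#' row-major upper-triangle order, mirrors them, and zeroes the diagonal.
#'
#' @param v Numeric vector of length N(N-1)/2.
#' @param n_regions Matrix order N; inferred from `length(v)` when omitted.
#' @return Symmetric N x N matrix with zero diagonal.
#' @export
devectorize <- function(v, n_regions = NULL) {
  d <- length(v)
  if (is.null(n_regions)) {
    n_regions <- (1 + sqrt(1 + 8 * d)) / 2
    if (abs(n_regions - round(n_regions)) > 1e-9) {
      stop("devectorize: length is not a triangular number", call. = FALSE)
    }
    n_regions <- as.integer(round(n_regions))
  }
  n_regions <- as.integer(n_regions)
  if (d != (n_regions * (n_regions - 1L)) %/% 2L) {
    stop("devectorize: vector length does not match matrix order", call. = FALSE)
  }
  a <- matrix(0, n_regions, n_regions)
  ta <- t(a)
  ta[lower.tri(ta)] <- v
  a <- t(ta)
  a + t(a)
}

#' Build the dynamic functional connectivity sequence
#'
#' Slides a window over the time series, computes per-window Pearson
#' correlation matrices, thresholds them into adjacency matrices, and stacks
#' the vectorized upper triangles into the g x d state observation matrix G
#' (d = N(N-1)/2). With the defaults and a 176 x 90 input, G is 157 x 4005.
#'
#' @param ts A [region_ts].
#' @param config A [window_config].
#' @return An object of class `connectivity_sequence` with elements
#'   `n_windows`, `matrices` (list of g thresholded adjacency matrices),
#'   `G` (g x d feature matrix), `window_starts`, and `config`.
#' @export
build_connectivity_sequence <- function(ts, config = window_config()) {
  stopifnot(inherits(ts, "region_ts"), inherits(config, "window_config"))
  n_t <- nrow(ts$values)
  n_regions <- ncol(ts$values)
  g <- count_windows(n_t, config$window, config$step)
  starts <- 1L + (seq_len(g) - 1L) * config$step
  d <- (n_regions * (n_regions - 1L)) %/% 2L

  mats <- vector("list", g)
  G <- matrix(NA_real_, g, d)
  for (k in seq_len(g)) {
    r <- window_correlation(ts, starts[k], config$window)
    a <- apply_threshold(r, config$threshold, config$mode)
    mats[[k]] <- a
    feat <- if (config$features == "thresholded") a else {
      raw <- abs(r); diag(raw) <- 0; raw
    }
    G[k, ] <- vectorize_upper(feat)
  }
  structure(
    list(n_windows = g, matrices = mats, G = G, window_starts = starts,
         region_labels = ts$region_labels, config = config),
    class = "connectivity_sequence"
  )
}

#' @export
print.connectivity_sequence <- function(x, ...) {
  cat(sprintf("<connectivity_sequence> %d windows, %d regions, G is %d x %d (%s, th = %g)\n",
              x$n_windows, length(x$region_labels), nrow(x$G), ncol(x$G),
              x$config$mode, x$config$threshold))
  invisible(x)
}
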