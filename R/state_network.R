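#' Partition the window timeline into steady and transition intervals
#'
#' Given the m - 1 estimated transition intervals, the g windows are split
#' into s = 2m - 1 contiguous sets S_1..S_s: even-indexed sets are the
#' transition intervals, odd-indexed sets the complementary steady gaps.
#' Every window belongs to exactly one set; an empty steady gap (two
#' transition intervals touching, or one touching the timeline edge) is an
#' error — re-estimate with a smaller mass fraction or fewer states.
#'
#' @param intervals List of m - 1 `transition_interval`s in increasing order.
#' @param n_windows Timeline length g.
#' @param m Number of states.
#' @return An object of class `state_partition` with `s`, `sets` (list of s
#'   integer vectors), and `kind` ("steady"/"transition" per set).
#' @export
build_partition <- function(intervals, n_windows, m) {
  m <- as.integer(m); g <- as.integer(n_windows)
  if (length(intervals) != m - 1L) {
    stop("build_partition: need exactly m - 1 transition intervals", call. = FALSE)
  }
  bounds <- t(vapply(intervals, function(iv) {
    as.integer(c(max(1, iv$t1), min(g, iv$t2)))
  }, integer(2)))
  if (m > 1L) {
    if (is.unsorted(bounds[, 1L], strictly = TRUE)) {
      stop("build_partition: transition intervals must be sorted", call. = FALSE)
    }
    if (any(bounds[, 2L] < bounds[, 1L])) {
      stop("build_partition: interval clipped to nothing", call. = FALSE)
    }
  }
  sets <- vector("list", 2L * m - 1L)
  kind <- rep(c("steady", "transition"), length.out = 2L * m - 1L)
  prev_end <- 0L
  for (q in seq_len(m - 1L)) {
    t1 <- bounds[q, 1L]; t2 <- bounds[q, 2L]
    if (t1 <= prev_end + 1L) {
      stop(sprintf("build_partition: empty steady gap before transition %d (overlapping intervals; increase alpha separation or reduce m)", q),
           call. = FALSE)
    }
    sets[[2L * q - 1L]] <- (prev_end + 1L):(t1 - 1L)
    sets[[2L * q]] <- t1:t2
    prev_end <- t2
  }
  if (prev_end >= g) {
    stop("build_partition: no steady windows after the last transition", call. = FALSE)
  }
  sets[[2L * m - 1L]] <- (prev_end + 1L):g
  structure(list(s = 2L * m - 1L, sets = sets, kind = kind, n_windows = g),
            class = "state_partition")
}

#' @export
print.state_partition <- function(x, ...) {
  cat(sprintf("<state_partition> s = %d intervals over %d windows\n", x$s, x$n_windows))
  for (i in seq_len(x$s)) {
    cat(sprintf("  S_%d (%s): %d..%d\n", i, x$kind[i],
                min(x$sets[[i]]), max(x$sets[[i]])))
  }
  invisible(x)
}

#' Reference 9-interval layout for 157-window recordings
#'
#' The fixed partition observed for the healthy-control group on recordings
#' with 157 windows (m = 5 steady states and 4 transition intervals):
#' steady sets 1-9, 16-50, 56-85, 91-125, 131-157 alternating with
#' transition sets 10-15, 51-55, 86-90, 126-130. Windows on a boundary are
#' assigned to the transition interval.
#'
#' @param n_windows Must be 157.
#' @return A [build_partition()]-style `state_partition` with s = 9.
#' @export
partition_hc9 <- function(n_windows = 157L) {
  if (as.integer(n_windows) != 157L) {
    stop("partition_hc9: this layout is defined for exactly 157 windows", call. = FALSE)
  }
  iv <- function(q, t1, t2) structure(list(q = q, t1 = t1, t2 = t2,
                                           alpha = NA_real_, mass = NA_real_),
                                      class = "transition_interval")
  build_partition(list(iv(1L, 10L, 15L), iv(2L, 51L, 55L),
                       iv(3L, 86L, 90L), iv(4L, 126L, 130L)),
                  n_windows = 157L, m = 5L)
}

#' Average the window networks of one state interval
#'
#' Element-wise mean of the thresholded adjacency matrices whose window
#' indices fall in `windows`.
#'
#' @param conn A [build_connectivity_sequence()] result.
#' @param windows Non-empty integer vector of window indices.
#' @return N x N symmetric matrix with entries in \[0, 1\].
#' @export
average_state_matrix <- function(conn, windows) {
  stopifnot(inherits(conn, "connectivity_sequence"))
  windows <- as.integer(windows)
  if (length(windows) == 0L) stop("average_state_matrix: empty window set", call. = FALSE)
  if (any(windows < 1L | windows > conn$n_windows)) {
    stop("average_state_matrix: window index out of range", call. = FALSE)
  }
  Reduce(`+`, conn$matrices[windows]) / length(windows)
}

#' Per-subject state networks
#'
#' Applies [average_state_matrix()] to every interval of a partition,
#' yielding the subject's s state networks.
#'
#' @param conn A `connectivity_sequence`.
#' @param partition A [state_partition].
#' @return List of s N x N matrices, with the partition's `kind` attached as
#'   an attribute.
#' @export
subject_state_networks <- function(conn, partition) {
  stopifnot(inherits(partition, "state_partition"))
  if (partition$n_windows != conn$n_windows) {
    stop("subject_state_networks: partition and sequence disagree on window count",
         call. = FALSE)
  }
  out <- lapply(partition$sets, function(w) average_state_matrix(conn, w))
  attr(out, "kind") <- partition$kind
  out
}

#' Group-average state networks
#'
#' Element-wise mean of each state's network across subjects.
#'
#' @param subject_networks List with one element per subject, each a list of
#'   s matrices as returned by [subject_state_networks()].
#' @return List of s N x N group state networks.
#' @export
group_state_networks <- function(subject_networks) {
  n_sub <- length(subject_networks)
  if (n_sub < 1L) stop("group_state_networks: need at least one subject", call. = FALSE)
  s <- length(subject_networks[[1L]])
  dims <- dim(subject_networks[[1L]][[1L]])
  for (sn in subject_networks) {
    if (length(sn) != s || !all(vapply(sn, function(x) identical(dim(x), dims), logical(1)))) {
      stop("group_state_networks: inconsistent shapes across subjects", call. = FALSE)
    }
  }
  out <- lapply(seq_len(s), function(i) {
    Reduce(`+`, lapply(subject_networks, `[[`, i)) / n_sub
  })
  attr(out, "kind") <- attr(subject_networks[[1L]], "kind")
  out
}

#' Neighbor topology overlap of one node between two state networks
#'
#' Similarity of node i's weighted neighborhood in networks `za` and `zb`
#' (entries in \[0, 1\], zero diagonal). The default form is
#' C_i = sum_j (1 - |a_ij - b_ij|) a_ij b_ij / sqrt(sum_j a_ij * sum_j b_ij);
#' `mode = "classic"` drops the (1 - |a - b|) factor, recovering the standard
#' temporal topological overlap. A node with zero strength in either network
#' scores 0. For identical binary networks both forms give 1 at every node
#' with positive degree.
#'
#' @param za,zb N x N weighted adjacency matrices, entries in \[0, 1\].
#' @param node Node index i.
#' @param mode `"default"` or `"classic"`.
#' @return Overlap coefficient in \[0, 1\].
#' @export
node_overlap <- function(za, zb, node, mode = c("default", "classic")) {
  mode <- match.arg(mode)
  node_overlap_all(za, zb, mode)[node]
}

# Vectorized per-node overlap used by node_overlap() and network_overlap().
node_overlap_all <- function(za, zb, mode = c("default", "classic")) {
  mode <- match.arg(mode)
  za <- as.matrix(za); zb <- as.matrix(zb)
  if (!identical(dim(za), dim(zb))) {
    stop("node overlap: matrices must have identical shape", call. = FALSE)
  }
  if (min(za, zb) < -1e-12 || max(za, zb) > 1 + 1e-12) {
    stop("node overlap: entries must lie in [0, 1]", call. = FALSE)
  }
  w <- if (mode == "default") (1 - abs(za - zb)) else 1
  num <- rowSums(w * za * zb)
  denom <- sqrt(rowSums(za) * rowSums(zb))
  ifelse(denom > 0, num / denom, 0)
}

#' Network-level neighbor topology overlap
#'
#' Mean of the per-node overlap coefficients over all N nodes; symmetric in
#' its arguments and bounded by \[0, 1\].
#'
#' @inheritParams node_overlap
#' @return Scalar overlap coefficient in \[0, 1\].
#' @export
network_overlap <- function(za, zb, mode = c("default", "classic")) {
  mean(node_overlap_all(za, zb, mode))
}

#' Pairwise overlap matrix of the group state networks
#'
#' Computes [network_overlap()] for every pair of state networks, giving the
#' s x s overlap matrix (9 x 9 for m = 5). The diagonal is reported as 0 by
#' convention.
#'
#' @param group_networks List of s state networks
#'   (see [group_state_networks()]).
#' @param mode Overlap mode, see [node_overlap()].
#' @return An object of class `overlap_matrix`: the s x s symmetric numeric
#'   matrix with a `mode` attribute.
#' @export
overlap_matrix <- function(group_networks, mode = c("default", "classic")) {
  mode <- match.arg(mode)
  s <- length(group_networks)
  if (s < 2L) stop("overlap_matrix: need at least two state networks", call. = FALSE)
  C <- matrix(0, s, s)
  for (a in seq_len(s - 1L)) {
    for (b in (a + 1L):s) {
      C[a, b] <- C[b, a] <- network_overlap(group_networks[[a]],
                                            group_networks[[b]], mode)
    }
  }
  dimnames(C) <- list(paste0("S", seq_len(s)), paste0("S", seq_len(s)))
  structure(C, mode = mode, class = c("overlap_matrix", "matrix", "array"))
}

#' Off-diagonal overlap values
#'
#' The upper-triangle, off-diagonal entries of an overlap matrix as a plain
#' vector (36 values for s = 9) — the unit of analysis for the group
#' comparison.
#'
#' @param om An [overlap_matrix()] result (or any symmetric matrix).
#' @return Numeric vector of length s(s-1)/2.
#' @export
overlap_values <- function(om) {
  vectorize_upper(unclass(om))
}
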