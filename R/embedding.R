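#' Embedding configuration
#'
#' Settings for the low-dimensional embedding of the state observation
#' matrix. The default method is exact t-SNE (quadratic in the number of
#' windows, which is small here); `"pca"` is available as a fast linear
#' alternative.
#'
#' @param method `"tsne"` (default) or `"pca"`.
#' @param perplexity t-SNE perplexity; must be smaller than the number of
#'   windows (default 30).
#' @param n_iterations Gradient-descent iterations for t-SNE (default 1000).
#' @param seed Integer seed; fully determines the embedding.
#' @return An object of class `embedding_config`.
#' @export
embedding_config <- function(method = c("tsne", "pca"), perplexity = 30,
                             n_iterations = 1000L, seed = 1L) {
  method <- match.arg(method)
  if (perplexity <= 0) stop("embedding_config: perplexity must be positive",
                            call. = FALSE)
  if (n_iterations < 1L) stop("embedding_config: n_iterations must be >= 1",
                              call. = FALSE)
  structure(
    list(method = method, perplexity = perplexity,
         n_iterations = as.integer(n_iterations), seed = as.integer(seed)),
    class = "embedding_config"
  )
}

#' Embed the state observation matrix in two dimensions
#'
#' Maps the g window-network feature vectors (rows of G) to 2-D coordinates.
#' For `method = "tsne"` this runs an exact t-SNE: per-row affinities are
#' tuned by bisection to the target perplexity, and the Kullback-Leibler
#' divergence is minimized by gradient descent with early exaggeration,
#' momentum, and adaptive per-coordinate gains, from a small random Gaussian
#' initialization drawn under `cfg$seed`. Identical inputs and seed give
#' identical coordinates.
#'
#' @param G g x d numeric matrix (rows = windows).
#' @param cfg An [embedding_config].
#' @return An object of class `state_embedding` with elements `coords`
#'   (g x 2 matrix) and `config`.
#' @export
embed_states <- function(G, cfg = embedding_config()) {
  stopifnot(inherits(cfg, "embedding_config"))
  G <- as.matrix(G)
  g <- nrow(G)
  if (g < 5L) stop("embed_states: need at least 5 windows", call. = FALSE)
  if (!all(is.finite(G))) stop("embed_states: non-finite entries in G", call. = FALSE)
  coords <- switch(
    cfg$method,
    tsne = {
      if (cfg$perplexity >= g) {
        stop("embed_states: perplexity must be smaller than the number of windows",
             call. = FALSE)
      }
      set.seed(cfg$seed)
      y0 <- matrix(stats::rnorm(g * 2L, sd = 1e-4), g, 2L)
      tsne_embed_cpp(G, y0, cfg$perplexity, cfg$n_iterations)
    },
    pca = {
      p <- stats::prcomp(G, center = TRUE, scale. = FALSE)
      sc <- p$x[, seq_len(min(2L, ncol(p$x))), drop = FALSE]
      if (ncol(sc) < 2L) sc <- cbind(sc, 0)
      unname(sc)
    }
  )
  structure(list(coords = coords, config = cfg), class = "state_embedding")
}

#' Cluster the embedded windows into m states
#'
#' k-means with `m` centers and 10 random restarts on the 2-D coordinates.
#' If k-means reports an empty cluster the call is retried with a fresh
#' initialization, up to `retries` times, then fails.
#'
#' @param emb A `state_embedding` from [embed_states()].
#' @param m Number of states.
#' @param seed Integer seed for the k-means initialization.
#' @param retries Retry budget for empty-cluster failures (default 5).
#' @return Integer vector of raw cluster labels in 1..m, one per window.
#' @export
cluster_embedding <- function(emb, m, seed = 1L, retries = 5L) {
  stopifnot(inherits(emb, "state_embedding"))
  g <- nrow(emb$coords)
  m <- as.integer(m)
  if (m < 1L || m > g) stop("cluster_embedding: need 1 <= m <= number of windows",
                            call. = FALSE)
  if (m == 1L) return(rep(1L, g))
  for (attempt in seq_len(retries + 1L)) {
    set.seed(as.integer(seed) + 100000L * (attempt - 1L))
    fit <- tryCatch(
      stats::kmeans(emb$coords, centers = m, nstart = 10L, iter.max = 100L),
      error = function(e) e
    )
    if (!inherits(fit, "error")) return(as.integer(fit$cluster))
  }
  stop("cluster_embedding: k-means failed repeatedly (empty cluster)", call. = FALSE)
}

# Sliding mode filter: replace each label by the most frequent label in a
# centered window (shrunk at the edges); ties keep the current label when it
# participates, otherwise take the smallest label.
mode_filter <- function(labels, width = 5L) {
  g <- length(labels)
  half <- width %/% 2L
  out <- labels
  for (i in seq_len(g)) {
    win <- labels[max(1L, i - half):min(g, i + half)]
    tab <- table(win)
    best <- as.integer(names(tab)[tab == max(tab)])
    out[i] <- if (labels[i] %in% best) labels[i] else min(best)
  }
  out
}

#' Temporal segmentation of raw cluster labels
#'
#' Enforces temporal contiguity on raw per-window cluster labels: a sliding
#' mode filter (width `filter_width`) removes isolated flips, then runs
#' shorter than `min_run` windows are merged into their longer neighbor until
#' exactly `m` maximal runs remain. Runs are finally relabeled 1..m in order
#' of first occurrence. Fails when no sequence of merges reaches exactly `m`
#' runs all of length at least `min_run` — e.g. when the raw labels
#' alternate with no temporal structure.
#'
#' @param labels Integer vector of raw cluster labels.
#' @param m Number of states.
#' @param filter_width Mode-filter window width (default 5).
#' @param min_run Minimum run length; shorter runs are merge candidates
#'   (default 3).
#' @return An object of class `segmentation` with elements `m`, `labels`
#'   (temporally ordered state ids 1..m), `run_lengths`, and
#'   `critical_points` (the last window index of each of the first m - 1
#'   runs).
#' @export
temporal_segmentation <- function(labels, m, filter_width = 5L, min_run = 3L) {
  labels <- as.integer(labels)
  m <- as.integer(m)
  if (length(unique(labels)) < m) {
    stop("temporal_segmentation: fewer than m distinct labels present", call. = FALSE)
  }
  filtered <- mode_filter(labels, filter_width)
  runs <- rle(filtered)
  while (length(runs$lengths) > m) {
    short <- which(runs$lengths < min_run)
    if (length(short) == 0L) {
      stop("temporal_segmentation: cannot reduce to m runs (no run shorter than min_run)",
           call. = FALSE)
    }
    idx <- short[which.min(runs$lengths[short])]
    n_runs <- length(runs$lengths)
    neighbor <- if (idx == 1L) 2L
      else if (idx == n_runs) n_runs - 1L
      else if (runs$lengths[idx - 1L] >= runs$lengths[idx + 1L]) idx - 1L
      else idx + 1L
    runs$values[idx] <- runs$values[neighbor]
    runs <- rle(inverse.rle(runs))
  }
  if (length(runs$lengths) < m) {
    stop("temporal_segmentation: merging collapsed below m runs", call. = FALSE)
  }
  if (any(runs$lengths < min_run)) {
    stop("temporal_segmentation: cannot reduce to m runs of length >= min_run (no temporal structure)",
         call. = FALSE)
  }
  run_lengths <- runs$lengths
  final <- rep.int(seq_len(m), run_lengths)
  structure(
    list(m = m, labels = final, run_lengths = run_lengths,
         critical_points = as.integer(cumsum(run_lengths)[seq_len(m - 1L)])),
    class = "segmentation"
  )
}

#' State-transition critical points
#'
#' The critical point of transition q is the last window index of temporal
#' run q, for q = 1..m-1; the final run has no outgoing transition.
#'
#' @param seg A `segmentation` from [temporal_segmentation()].
#' @return Integer vector of m - 1 strictly increasing window indices.
#' @export
critical_points <- function(seg) {
  stopifnot(inherits(seg, "segmentation"))
  seg$critical_points
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %d states over %d windows; critical points: %s\n",
              x$m, length(x$labels),
              paste(x$critical_points, collapse = ", ")))
  invisible(x)
}
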