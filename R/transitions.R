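#' Repeat embedding and segmentation, accumulating critical-point histograms
#'
#' The 2-D embedding of the window networks is stochastic: its layout depends
#' on the initialization. The pipeline therefore repeats
#' embed -> cluster -> temporal segmentation `reps` times with seeds
#' `base_seed .. base_seed + reps - 1` and counts, for every transition
#' q = 1..m-1, how often its critical point falls on each window index.
#' Repetitions whose labels cannot be segmented into exactly m temporal runs
#' are excluded from the counts but reported.
#'
#' @param G g x d state observation matrix.
#' @param m Number of states (default 5).
#' @param reps Number of repetitions (default 1000).
#' @param base_seed Integer; repetition r uses seed `base_seed + r - 1`.
#' @param embedding Template [embedding_config()]; its seed field is overridden
#'   per repetition.
#' @param filter_width,min_run Passed to [temporal_segmentation()].
#' @return An object of class `cp_histogram` with elements `m`, `n_windows`,
#'   `reps_attempted`, `reps_successful`, and `counts`, an (m-1) x g integer
#'   matrix whose row q sums to `reps_successful`.
#' @export
repeat_runs <- function(G, m = 5L, reps = 1000L, base_seed = 1L,
                        embedding = embedding_config(),
                        filter_width = 5L, min_run = 3L) {
  G <- as.matrix(G)
  m <- as.integer(m); reps <- as.integer(reps)
  if (reps < 1L) stop("repeat_runs: reps must be >= 1", call. = FALSE)
  g <- nrow(G)
  counts <- matrix(0L, m - 1L, g)
  successes <- 0L
  for (r in seq_len(reps)) {
    seed_r <- as.integer(base_seed) + r - 1L
    cfg <- embedding
    cfg$seed <- seed_r
    seg <- tryCatch({
      emb <- embed_states(G, cfg)
      raw <- cluster_embedding(emb, m, seed = seed_r)
      temporal_segmentation(raw, m, filter_width, min_run)
    }, error = function(e) e)
    if (inherits(seg, "error")) next
    cps <- seg$critical_points
    for (q in seq_len(m - 1L)) {
      counts[q, cps[q]] <- counts[q, cps[q]] + 1L
    }
    successes <- successes + 1L
  }
  if (successes == 0L) {
    stop("repeat_runs: no repetition produced a valid segmentation", call. = FALSE)
  }
  structure(
    list(m = m, n_windows = g, reps_attempted = reps,
         reps_successful = successes, counts = counts),
    class = "cp_histogram"
  )
}

#' @export
print.cp_histogram <- function(x, ...) {
  cat(sprintf("<cp_histogram> %d states, %d windows; %d/%d repetitions segmented\n",
              x$m, x$n_windows, x$reps_successful, x$reps_attempted))
  invisible(x)
}

#' Estimate a transition interval from a critical-point histogram
#'
#' The transition interval P_q = (t1, t2) is the shortest contiguous window
#' range holding at least a fraction `alpha` of transition q's critical-point
#' mass; among equally short ranges the one with the smaller t1 wins.
#'
#' @param hist A `cp_histogram` from [repeat_runs()], or a bare numeric count vector.
#' @param q Transition index in 1..m-1 (ignored for a bare vector).
#' @param alpha Mass fraction the interval must contain (default 0.9).
#' @return An object of class `transition_interval` with fields `q`, `t1`,
#'   `t2`, `alpha`, and `mass` (the fraction actually covered).
#' @export
estimate_interval <- function(hist, q = 1L, alpha = 0.9) {
  counts <- if (inherits(hist, "cp_histogram")) hist$counts[q, ] else as.numeric(hist)
  g <- length(counts)
  total <- sum(counts)
  if (total <= 0) stop("estimate_interval: histogram row has no mass", call. = FALSE)
  need <- alpha * total
  prefix <- c(0, cumsum(counts))
  for (len in seq_len(g)) {
    starts <- seq_len(g - len + 1L)
    mass <- prefix[starts + len] - prefix[starts]
    hit <- which(mass >= need - 1e-12)
    if (length(hit) > 0L) {
      t1 <- starts[hit[1L]]
      return(structure(
        list(q = as.integer(q), t1 = t1, t2 = t1 + len - 1L,
             alpha = alpha, mass = mass[hit[1L]] / total),
        class = "transition_interval"
      ))
    }
  }
  stop("estimate_interval: no covering interval found", call. = FALSE)  # unreachable
}

#' @export
print.transition_interval <- function(x, ...) {
  cat(sprintf("<transition_interval> q = %d: [%d, %d] (alpha = %g, mass = %.3f)\n",
              x$q, x$t1, x$t2, x$alpha, x$mass))
  invisible(x)
}

#' Overlap between two transition intervals
#'
#' Number of window indices shared by two inclusive intervals:
#' `max(0, min(t2a, t2b) - max(t1a, t1b) + 1)`.
#'
#' @param a,b `transition_interval`s, or length-2 vectors `c(t1, t2)`.
#' @return Non-negative integer count of shared windows.
#' @export
interval_overlap <- function(a, b) {
  as_pair <- function(x) {
    if (inherits(x, "transition_interval")) c(x$t1, x$t2) else as.integer(x[1:2])
  }
  a <- as_pair(a); b <- as_pair(b)
  max(0L, min(a[2L], b[2L]) - max(a[1L], b[1L]) + 1L)
}

#' Interval coincidence degree of a group
#'
#' For each subject y with transition intervals P_1..P_{m-1} over g_y windows,
#' the coincidence degree is the total overlap of adjacent interval pairs
#' normalized by the timeline length, Q_y = sum_x R_x / g_y with
#' R_x = overlap(P_x, P_{x+1}); the group value is the arithmetic mean of the
#' Q_y. Large values indicate smeared, unstable transitions whose intervals
#' run into each other.
#'
#' @param interval_lists List with one element per subject, each a list of the
#'   subject's m - 1 `transition_interval`s in transition order.
#' @param n_windows Timeline length g: a single value or one per subject.
#' @param group Optional group label carried through to the result.
#' @return An object of class `coincidence_result` with per-subject `Q`,
#'   group mean `Q_bar`, and `group`.
#' @export
coincidence_degree <- function(interval_lists, n_windows, group = NA_character_) {
  n_sub <- length(interval_lists)
  if (n_sub < 1L) stop("coincidence_degree: need at least one subject", call. = FALSE)
  g_y <- rep_len(as.numeric(n_windows), n_sub)
  Q <- vapply(seq_len(n_sub), function(y) {
    ivs <- interval_lists[[y]]
    if (length(ivs) < 2L) return(0)
    overlaps <- vapply(seq_len(length(ivs) - 1L), function(x) {
      interval_overlap(ivs[[x]], ivs[[x + 1L]])
    }, numeric(1))
    sum(overlaps) / g_y[y]
  }, numeric(1))
  structure(list(Q = Q, Q_bar = mean(Q), group = group),
            class = "coincidence_result")
}

#' @export
print.coincidence_result <- function(x, ...) {
  cat(sprintf("<coincidence_result>%s n = %d subjects, Q_bar = %.4f\n",
              if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
              length(x$Q), x$Q_bar))
  invisible(x)
}

#' Instantaneous state conversion rate within a transition interval
#'
#' Summarizes how the critical-point mass of transition q accrues across its
#' interval \[t1, t2\]. The default `"cumulative"` form is
#' lambda(k) = sum(N\[t1..k\]) / sum(N\[t1..t2\]) — the fraction of the
#' interval's transition mass accrued by window k; it is non-decreasing and
#' reaches 1 at t2. The `"density"` form additionally divides by the interval
#' length (t2 - t1 + 1), giving a per-window average accrual. Both are
#' operationalizations of the same trend statistic; outputs carry the form
#' used.
#'
#' @param hist A `cp_histogram` from [repeat_runs()], or a bare numeric count vector.
#' @param interval A `transition_interval` from [estimate_interval()] (its `q` selects the histogram
#'   row).
#' @param form `"cumulative"` (default) or `"density"`.
#' @return An object of class `conversion_curve` with `k` (window indices
#'   t1..t2), `lambda`, `q`, and `form`.
#' @export
conversion_rate <- function(hist, interval, form = c("cumulative", "density")) {
  form <- match.arg(form)
  stopifnot(inherits(interval, "transition_interval"))
  counts <- if (inherits(hist, "cp_histogram")) {
    hist$counts[interval$q, ]
  } else as.numeric(hist)
  ks <- interval$t1:interval$t2
  mass <- sum(counts[ks])
  if (mass <= 0) stop("conversion_rate: interval holds no mass", call. = FALSE)
  lam <- cumsum(counts[ks]) / mass
  if (form == "density") lam <- lam / length(ks)
  structure(list(k = ks, lambda = lam, q = interval$q, form = form),
            class = "conversion_curve")
}

#' @export
print.conversion_curve <- function(x, ...) {
  cat(sprintf("<conversion_curve> q = %d, %s form, k in [%d, %d], lambda(t2) = %.3f\n",
              x$q, x$form, x$k[1L], x$k[length(x$k)], x$lambda[length(x$lambda)]))
  invisible(x)
}
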