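#' Pipeline run configuration
#'
#' Bundles every stage's tunable parameters with their defaults: 20-point
#' windows at step 1, |r| threshold 0.5, m = 5 states, 1000 repetitions,
#' interval mass fraction 0.9, default overlap mode, cumulative conversion
#' form, and a base seed. Serializes to/from JSON so each run can record the
#' resolved configuration next to its outputs.
#'
#' @param window,step,threshold,mode See [window_config()].
#' @param m Number of states (default 5).
#' @param reps Embedding/clustering repetitions per subject (default 1000).
#' @param alpha Interval mass fraction (default 0.9).
#' @param perplexity,n_iterations See [embedding_config()].
#' @param overlap_mode `"default"` or `"classic"`, see [node_overlap()].
#' @param lambda_form `"cumulative"` or `"density"`, see [conversion_rate()].
#' @param base_seed Integer base seed; subject y's repetitions use seeds
#'   `base_seed + (y - 1) * reps + (0 .. reps - 1)`.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(window = 20L, step = 1L, threshold = 0.5,
                       mode = "weighted_abs", m = 5L, reps = 1000L,
                       alpha = 0.9, perplexity = 30, n_iterations = 1000L,
                       overlap_mode = "default", lambda_form = "cumulative",
                       base_seed = 1L) {
  cfg <- list(window = as.integer(window), step = as.integer(step),
              threshold = threshold, mode = mode, m = as.integer(m),
              reps = as.integer(reps), alpha = alpha,
              perplexity = perplexity, n_iterations = as.integer(n_iterations),
              overlap_mode = overlap_mode, lambda_form = lambda_form,
              base_seed = as.integer(base_seed))
  window_config(cfg$window, cfg$step, cfg$threshold, cfg$mode)  # validates
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path JSON file written by [write_run_config()].
#' @export
read_run_config <- function(path) {
  do.call(run_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Analyze one subject: connectivity sequence -> repeated segmentation ->
# per-transition intervals. Returns NULL (with a message) on failure.
analyze_subject <- function(ts, config, subject_seed, subject_id = "?") {
  res <- tryCatch({
    conn <- build_connectivity_sequence(
      ts, window_config(config$window, config$step, config$threshold, config$mode))
    emb_cfg <- embedding_config(perplexity = config$perplexity,
                                n_iterations = config$n_iterations)
    hist <- repeat_runs(conn$G, m = config$m, reps = config$reps,
                        base_seed = subject_seed, embedding = emb_cfg)
    intervals <- lapply(seq_len(config$m - 1L), function(q) {
      estimate_interval(hist, q, config$alpha)
    })
    list(conn = conn, hist = hist, intervals = intervals)
  }, error = function(e) e)
  if (inherits(res, "error")) {
    message(sprintf("subject %s: analysis failed (%s)", subject_id,
                    conditionMessage(res)))
    return(NULL)
  }
  res
}

# Group-level analysis from per-subject results: coincidence degree, pooled
# histogram -> partition -> state networks -> overlap matrix.
analyze_group <- function(subject_results, config, group = NA_character_) {
  ok <- !vapply(subject_results, is.null, logical(1))
  res <- subject_results[ok]
  if (length(res) == 0L) stop(sprintf("group %s: no analyzable subjects", group),
                              call. = FALSE)
  g <- res[[1L]]$conn$n_windows
  coincidence <- coincidence_degree(lapply(res, `[[`, "intervals"), g, group)

  pooled <- res[[1L]]$hist
  if (length(res) > 1L) {
    for (r in res[-1L]) pooled$counts <- pooled$counts + r$hist$counts
    pooled$reps_attempted <- sum(vapply(res, function(r) r$hist$reps_attempted, numeric(1)))
    pooled$reps_successful <- sum(vapply(res, function(r) r$hist$reps_successful, numeric(1)))
  }
  group_intervals <- lapply(seq_len(config$m - 1L), function(q) {
    estimate_interval(pooled, q, config$alpha)
  })
  partition <- build_partition(group_intervals, g, config$m)
  subj_nets <- lapply(res, function(r) subject_state_networks(r$conn, partition))
  group_nets <- group_state_networks(subj_nets)
  om <- overlap_matrix(group_nets, config$overlap_mode)
  list(group = group, n_subjects = length(res), n_excluded = sum(!ok),
       coincidence = coincidence, pooled_hist = pooled,
       intervals = group_intervals, partition = partition,
       group_networks = group_nets, overlap = om)
}

#' Run the full pipeline over a subject manifest
#'
#' Executes, per subject, windowed connectivity construction and `reps`
#' embedding/segmentation repetitions; per group, the interval coincidence
#' degree, a pooled critical-point histogram, the steady/transition
#' partition, group state networks, and the overlap matrix; and, when the
#' manifest holds exactly two groups, one-way ANOVAs on the per-subject
#' coincidence degrees and on the off-diagonal overlap coefficients.
#' Subjects whose analysis fails are excluded with a message and counted.
#' When `outdir` is given, per-group histograms and overlap matrices (CSV),
#' a JSON summary, and the resolved configuration are written there.
#'
#' @param manifest Manifest data frame (`subject_id`, `file`, `group`) or
#'   path to one; alternatively supply `subjects` directly.
#' @param config A [run_config()].
#' @param subjects Optional named list of [region_ts] keyed like
#'   `manifest$subject_id`, bypassing file reads (used by the simulator and
#'   tests).
#' @param outdir Optional output directory.
#' @return List with per-`groups` results (see Details), `comparison`
#'   (ANOVA results or NULL), and `config`.
#' @export
run_pipeline <- function(manifest, config = run_config(), subjects = NULL,
                         outdir = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(is.data.frame(manifest), inherits(config, "run_config"))
  group_names <- unique(manifest$group)

  subject_results <- vector("list", nrow(manifest))
  names(subject_results) <- manifest$subject_id
  for (i in seq_len(nrow(manifest))) {
    ts <- if (!is.null(subjects)) subjects[[manifest$subject_id[i]]]
          else read_region_ts(manifest$file[i])
    seed_i <- config$base_seed + (i - 1L) * config$reps
    subject_results[[i]] <- analyze_subject(ts, config, seed_i,
                                            manifest$subject_id[i])
  }

  groups <- lapply(group_names, function(gn) {
    analyze_group(subject_results[manifest$group == gn], config, gn)
  })
  names(groups) <- group_names

  comparison <- NULL
  if (length(groups) == 2L) {
    safe_anova <- function(a, b, what) {
      tryCatch(one_way_anova(a, b, group_names), error = function(e) {
        message(sprintf("comparison (%s) skipped: %s", what, conditionMessage(e)))
        NULL
      })
    }
    comparison <- list(
      coincidence = safe_anova(groups[[1L]]$coincidence$Q,
                               groups[[2L]]$coincidence$Q, "coincidence"),
      overlap = safe_anova(overlap_values(groups[[1L]]$overlap),
                           overlap_values(groups[[2L]]$overlap), "overlap")
    )
  } else {
    message("comparison stage skipped: need exactly two groups")
  }

  out <- list(groups = groups, comparison = comparison, config = config)
  if (!is.null(outdir)) write_pipeline_outputs(out, outdir)
  out
}

# Writes the delimited and JSON artifacts of a pipeline run.
write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(result$config, file.path(outdir, "config.json"))
  summary <- list()
  for (gn in names(result$groups)) {
    gr <- result$groups[[gn]]
    utils::write.csv(gr$pooled_hist$counts,
                     file.path(outdir, paste0(gn, "_histogram.csv")),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(unclass(gr$overlap)),
                     file.path(outdir, paste0(gn, "_overlap.csv")),
                     row.names = TRUE)
    summary[[gn]] <- list(
      n_subjects = gr$n_subjects, n_excluded = gr$n_excluded,
      Q = gr$coincidence$Q, Q_bar = gr$coincidence$Q_bar,
      intervals = lapply(gr$intervals, function(iv) c(t1 = iv$t1, t2 = iv$t2)),
      mean_overlap = mean(overlap_values(gr$overlap))
    )
  }
  if (!is.null(result$comparison)) {
    summary$comparison <- lapply(result$comparison, as.list)
  }
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
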