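#' Read a region time-series file
#'
#' Reads a delimited text file with a header row of region labels and one
#' row per time point (the format written by [write_cohort()]). The
#' delimiter (comma or tab) is auto-detected from the header line.
#'
#' @param path File path.
#' @param tr_seconds Repetition time metadata (default 2).
#' @param transpose Set `TRUE` when the file stores regions as rows.
#' @return A [region_ts].
#' @export
read_region_ts <- function(path, tr_seconds = 2, transpose = FALSE) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  x <- as.matrix(df)
  if (transpose) x <- t(x)
  region_ts(x, tr_seconds = tr_seconds)
}

#' Write a synthetic cohort to disk
#'
#' Writes one CSV per subject (header = region labels, rows = time points),
#' a JSON ground-truth file, and a manifest CSV with columns `subject_id`,
#' `file`, `group`.
#'
#' @param cohort A [generate_bold()] result.
#' @param dir Output directory (created if needed).
#' @param group Group label recorded in the manifest (e.g. "HC").
#' @param prefix Subject id prefix (default the group label).
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort <- function(cohort, dir, group = "HC", prefix = group) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_sub <- length(cohort$subjects)
  ids <- sprintf("%s%02d", prefix, seq_len(n_sub))
  files <- file.path(dir, paste0(ids, ".csv"))
  for (y in seq_len(n_sub)) {
    utils::write.csv(as.data.frame(cohort$subjects[[y]]$values),
                     files[y], row.names = FALSE)
  }
  truth <- lapply(seq_len(n_sub), function(y) {
    tr <- cohort$truth[[y]]
    list(subject_id = ids[y], labels = tr$labels, boundaries = tr$boundaries,
         ramps = lapply(tr$ramps, function(r) c(start = r[1L], end = r[2L])))
  })
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- data.frame(subject_id = ids, file = files, group = group,
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a subject manifest
#'
#' @param path CSV with columns `subject_id`, `file`, `group`. Relative file
#'   paths are resolved against the manifest's directory.
#' @return Data frame with those three columns.
#' @export
read_manifest <- function(path) {
  mf <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "file", "group")
  if (!all(need %in% names(mf))) {
    stop("read_manifest: manifest needs columns subject_id, file, group", call. = FALSE)
  }
  missing <- !file.exists(mf$file)
  if (any(missing)) {
    alt <- file.path(dirname(path), mf$file[missing])
    ok <- file.exists(alt)
    mf$file[missing][ok] <- alt[ok]
    if (any(!ok)) {
      stop(sprintf("read_manifest: missing time-series file(s): %s",
                   paste(mf$subject_id[missing][!ok], collapse = ", ")),
           call. = FALSE)
    }
  }
  mf[need]
}
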