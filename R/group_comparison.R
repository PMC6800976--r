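#' One-way ANOVA between two groups
#'
#' Standard one-way analysis of variance comparing two groups of values,
#' fitted with [stats::lm()]/[stats::anova()]. Returns the full
#' decomposition: between- and within-group sums of squares, degrees of
#' freedom, mean squares, the F statistic, and its p value. For two groups
#' of sizes n_a and n_b the degrees of freedom are
#' (1, n_a + n_b - 2, n_a + n_b - 1).
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param labels Optional length-2 character vector of group names.
#' @return An object of class `anova_result`.
#' @export
one_way_anova <- function(values_a, values_b, labels = c("A", "B")) {
  values_a <- as.numeric(values_a); values_b <- as.numeric(values_b)
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("one_way_anova: each group needs at least 2 values", call. = FALSE)
  }
  y <- c(values_a, values_b)
  if (stats::var(y) == 0) {
    stop("one_way_anova: all values identical (degenerate variance)", call. = FALSE)
  }
  grp <- factor(rep(labels, c(length(values_a), length(values_b))), levels = labels)
  tab <- stats::anova(stats::lm(y ~ grp))
  ss_b <- tab$`Sum Sq`[1L]; ss_w <- tab$`Sum Sq`[2L]
  df_b <- tab$Df[1L]; df_w <- tab$Df[2L]
  structure(
    list(groups = labels,
         n = c(length(values_a), length(values_b)),
         ss_between = ss_b, ss_within = ss_w, ss_total = ss_b + ss_w,
         df_between = df_b, df_within = df_w, df_total = df_b + df_w,
         ms_between = tab$`Mean Sq`[1L], ms_within = tab$`Mean Sq`[2L],
         f = tab$`F value`[1L], p = tab$`Pr(>F)`[1L]),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: %s (n = %d) vs %s (n = %d)\n",
              x$groups[1L], x$n[1L], x$groups[2L], x$n[2L]))
  cat(sprintf("%-16s %14s %6s %14s %10s %8s\n",
              "", "Sum of squares", "df", "Mean of squares", "F", "Sig."))
  cat(sprintf("%-16s %14.3f %6d %14.3f %10.3f %8.3f\n",
              "Between groups", x$ss_between, x$df_between, x$ms_between, x$f, x$p))
  cat(sprintf("%-16s %14.3f %6d %14.3f\n",
              "Within groups", x$ss_within, x$df_within, x$ms_within))
  cat(sprintf("%-16s %14.3f %6d\n", "Total", x$ss_total, x$df_total))
  invisible(x)
}

#' @export
as.list.anova_result <- function(x, ...) unclass(x)
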