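#' Replicate-aware cohort summary (SuperPlot statistics)
#'
#' Summarizes a per-cell statistic nested within biological replicates
#' (transfection days): the grand mean and SEM are pooled over all cells
#' (SEM = sd/sqrt(n) over all data points), while per-batch means are
#' computed for replicate-aware display.
#'
#' @param values Per-cell values.
#' @param batch Replicate batch label per cell (transfection day).
#' @param hours Optional recording time point per cell (24 or 48).
#' @param parameter_name,construct_label Labels carried in the output.
#' @return A `superplot_summary`: list with `grand_mean`, `sem`, `n_cells`,
#'   `per_batch_means` (data frame), `per_cell_values` (data frame) and a
#'   `single_value` flag (SEM set to 0 by convention when n = 1).
#' @export
#' @examples
#' superplot_summary(c(1, 2, 3), batch = c("TD1", "TD1", "TD2"))
superplot_summary <- function(values, batch = rep("TD1", length(values)),
                              hours = rep(NA_real_, length(values)),
                              parameter_name = NA_character_,
                              construct_label = NA_character_) {
  if (length(values) == 0) stop("empty input")
  n <- length(values)
  single <- n == 1
  per_batch <- vapply(split(values, batch), mean, numeric(1))
  structure(list(
    construct_label = construct_label, parameter_name = parameter_name,
    per_cell_values = data.frame(value = values, replicate_batch = batch,
                                 hours_post_transfection = hours),
    per_batch_means = data.frame(replicate_batch = names(per_batch),
                                 mean = unname(per_batch)),
    grand_mean = mean(values),
    sem = if (single) 0 else stats::sd(values) / sqrt(n),
    n_cells = n, single_value = single
  ), class = "superplot_summary")
}

#' @export
print.superplot_summary <- function(x, ...) {
  cat(sprintf("<superplot_summary> %s %s: %.3f +/- %.3f (mean +/- SEM, n = %d, %d batch(es))\n",
              x$construct_label, x$parameter_name, x$grand_mean, x$sem,
              x$n_cells, nrow(x$per_batch_means)))
  invisible(x)
}

#' Significance tier of a p-value
#'
#' Maps a p-value to the conventional tiers with closed upper bounds:
#' `***` for p <= 0.001 (highly significant), `**` for 0.001 < p <= 0.01
#' (very significant), `*` for 0.01 < p <= 0.05 (significant), `ns`
#' otherwise.
#'
#' @param p P-value(s) in (0, 1].
#' @return Character tier(s).
#' @export
significance_tier <- function(p) {
  ifelse(p <= 0.001, "***",
         ifelse(p <= 0.01, "**",
                ifelse(p <= 0.05, "*", "ns")))
}

#' Unpaired Student's t-test between wild type and a variant
#'
#' Classical equal-variance two-sided Student's t-test (Welch's correction
#' available via `welch = TRUE`), with the significance tier attached. Two
#' groups that are both constant and equal give t = 0, p = 1 by convention.
#' Groups smaller than 5 trigger a warning (small-n comparisons are
#' reported but weakly powered), not an error.
#'
#' @param group_a,group_b Numeric vectors, each n >= 2.
#' @param welch Use Welch's unequal-variance form.
#' @param parameter_name,label_a,label_b Labels carried in the output.
#' @return A `comparison_result`: list with `t`, `df`, `p_value`,
#'   `significance_tier`, group means and sizes.
#' @export
#' @examples
#' unpaired_t(c(1, 2, 3), c(4, 5, 6))
unpaired_t <- function(group_a, group_b, welch = FALSE,
                       parameter_name = NA_character_,
                       label_a = "A", label_b = "B") {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 values")
  if (length(group_a) < 5 || length(group_b) < 5)
    warning("group size below 5; comparison is weakly powered")
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0 &&
      mean(group_a) == mean(group_b)) {
    t_stat <- 0
    df <- length(group_a) + length(group_b) - 2
    p <- 1
  } else {
    tt <- stats::t.test(group_a, group_b, var.equal = !welch)
    t_stat <- unname(tt$statistic)
    df <- unname(tt$parameter)
    p <- tt$p.value
  }
  structure(list(parameter_name = parameter_name,
                 group_a = label_a, group_b = label_b,
                 t_statistic = t_stat, df = df, p_value = p,
                 significance_tier = significance_tier(p),
                 mean_a = mean(group_a), mean_b = mean(group_b),
                 n_a = length(group_a), n_b = length(group_b)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: %s (%.3f, n=%d) vs %s (%.3f, n=%d): t = %.3f, p = %.3g %s\n",
              x$parameter_name, x$group_a, x$mean_a, x$n_a, x$group_b,
              x$mean_b, x$n_b, x$t_statistic, x$p_value,
              x$significance_tier))
  invisible(x)
}
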