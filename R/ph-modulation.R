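#' Within-cell relative change of peak current and kinetics across pH
#'
#' Compares the same cell recorded under the 200-ms -20 mV pulse train at
#' the reference pH 7.4 and at a test pH. Per condition the last
#' `n_average` sweeps (the steady-state block of the condition) are
#' averaged; the peak-ratio is the magnitude ratio of the averaged peaks and
#' the tau-ratio the ratio of inactivation time constants fitted to the
#' averaged traces.
#'
#' @param rec_ref Recording at pH 7.4.
#' @param rec_test Recording at the test pH, same cell and protocol.
#' @param n_average Number of trailing sweeps averaged per condition.
#' @return Data frame row: `cell_id`, `construct`, `ph_test`, `peak_ratio`
#'   (I_pHX / I_pH7.4), `tau_ratio` (tau_inact pHX / tau_inact pH7.4),
#'   `replicate_batch`.
#' @export
ph_ratios <- function(rec_ref, rec_test, n_average = 3) {
  if (rec_ref$cell_id != rec_test$cell_id)
    stop("pH ratios must be computed within one cell")
  if (rec_ref$protocol$name != rec_test$protocol$name)
    stop("reference and test recordings must share the protocol")
  if (format_ph(rec_ref$ph) == format_ph(rec_test$ph))
    stop("reference and test pH must differ")

  avg <- function(rec) {
    k <- length(rec$sweeps)
    use <- max(1L, k - n_average + 1L):k
    sw <- rec$sweeps[[use[1]]]
    cur <- rowMeans(vapply(use, function(i) rec$sweeps[[i]]$current,
                           numeric(nrow(sw))))
    out <- sw
    out$current <- cur
    out
  }
  sw_ref <- avg(rec_ref)
  sw_test <- avg(rec_test)
  pk_ref <- peak_current(sw_ref)
  pk_test <- peak_current(sw_test)
  if (abs(pk_ref$i_peak) == 0) stop("reference peak current is zero")
  kin_ref <- fit_kinetics(sw_ref)
  kin_test <- fit_kinetics(sw_test)
  data.frame(cell_id = rec_ref$cell_id, construct = rec_ref$construct_label,
             ph_test = as.numeric(rec_test$ph),
             peak_ratio = abs(pk_test$i_peak) / abs(pk_ref$i_peak),
             tau_ratio = kin_test$tau_inact / kin_ref$tau_inact,
             replicate_batch = rec_ref$replicate_batch,
             stringsAsFactors = FALSE)
}

#' Paired t-test for within-cell pH comparisons
#'
#' Classical two-sided paired Student's t-test on per-cell differences. When
#' only one vector of per-cell ratios is given, the differences are taken
#' against the null ratio `mu` (1 by default), i.e. a one-sample t-test of
#' the ratios against 1.
#'
#' @param x Per-cell values at the test condition, or ratios.
#' @param y Optional per-cell values at the reference condition (paired
#'   with `x`).
#' @param mu Null value for the ratio-only form.
#' @return List with `t`, `df`, `p_value`, `mean_diff`, `n`.
#' @export
#' @examples
#' paired_test(c(1.2, 1.3, 1.25))  # ratios against 1
paired_test <- function(x, y = NULL, mu = 1) {
  d <- if (is.null(y)) x - mu else {
    if (length(x) != length(y)) stop("paired vectors must have equal length")
    x - y
  }
  d <- d[is.finite(d)]
  if (length(d) < 2) stop("at least 2 pairs are required")
  if (stats::sd(d) == 0)
    stop("zero variance of paired differences; t statistic undefined")
  tt <- stats::t.test(d, mu = 0)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = mean(d), n = length(d))
}

#' One-way ANOVA with Tukey HSD across constructs
#'
#' Tests whether per-cell pH ratios (or any per-cell statistic) differ
#' across constructs: a one-way ANOVA F test followed by Tukey's honestly
#' significant difference pairwise comparisons against the studentized
#' range distribution.
#'
#' @param values Numeric vector of per-cell values.
#' @param group Factor (or character) of the same length naming the
#'   construct of each value; every group needs n >= 2.
#' @return List with `f`, `df`, `p_value` (ANOVA) and `pairwise` (data
#'   frame: `comparison`, `diff`, `p_adj`).
#' @export
#' @examples
#' set.seed(1)
#' across_construct_test(rnorm(30), rep(c("WT", "A", "B"), each = 10))
across_construct_test <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("at least 2 groups are required")
  n_by <- table(group)
  if (any(n_by < 2)) stop("every group needs at least 2 values")
  if (stats::sd(values) == 0)
    stop("all values identical; ANOVA undefined (zero variance)")
  dat <- data.frame(values = values, group = group)
  fit <- stats::aov(values ~ group, data = dat)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  list(f = an[["F value"]][1],
       df = c(an[["Df"]][1], an[["Df"]][2]),
       p_value = an[["Pr(>F)"]][1],
       pairwise = data.frame(comparison = rownames(tk),
                             diff = tk[, "diff"],
                             p_adj = tk[, "p adj"],
                             row.names = NULL, stringsAsFactors = FALSE))
}
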