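#' Read a rare-variant table from TSV
#'
#' Parses a tab-separated variant table with one row per variant: genomic
#' locus, protein and coding change, case minor-allele frequency, one or
#' more population-control MAF columns, and optional pass-through
#' annotation columns (in-silico predictor verdicts, rsIDs, carrier sample
#' IDs). MAF columns are validated to lie in \[0, 0.5\]; malformed rows are
#' reported with their row numbers.
#'
#' @param path Path to the TSV. The package ships the CACNA1I case-cohort
#'   table as `system.file("extdata", "cacna1i_variants.tsv",
#'   package = "cav3ephys")`, also available via [cacna1i_variants()].
#' @param control_cols Names of control MAF columns that must parse as
#'   frequencies; defaults to every column ending in `_maf` other than
#'   `case_maf`.
#' @return Data frame of variants (class `variant_table`).
#' @export
read_variant_table <- function(path, control_cols = NULL) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  required <- c("locus", "aa_change", "case_maf")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0)
    stop("variant table is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (is.null(control_cols))
    control_cols <- setdiff(grep("_maf$", names(tab), value = TRUE),
                            "case_maf")
  if (length(control_cols) == 0)
    stop("variant table needs at least one control MAF column (*_maf)")

  for (col in c("case_maf", control_cols)) {
    val <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(val) & nzchar(tab[[col]]))
    if (length(bad) > 0)
      stop(sprintf("unparseable MAF in column '%s', row(s) %s", col,
                   paste(bad, collapse = ", ")))
    out_of_range <- which(val < 0 | val > 0.5)
    if (length(out_of_range) > 0)
      stop(sprintf("MAF outside [0, 0.5] in column '%s', row(s) %s", col,
                   paste(out_of_range, collapse = ", ")))
    tab[[col]] <- val
  }
  bad_locus <- which(!grepl("^[A-Za-z0-9_.]+:[0-9]+$", tab$locus))
  if (length(bad_locus) > 0)
    stop("unparseable locus in row(s) ", paste(bad_locus, collapse = ", "))
  class(tab) <- c("variant_table", "data.frame")
  tab
}

#' Shipped CACNA1I case-cohort variant table
#'
#' The ten rare heterozygous CACNA1I missense variants confirmed in the
#' 187-proband hemiplegic-migraine case cohort, with case MAF, gnomAD
#' non-Finnish European and UK Biobank control MAFs, and in-silico
#' predictor annotations (consumed as opaque columns, never computed).
#'
#' @return Data frame of 10 variants (see [read_variant_table()]).
#' @export
#' @examples
#' v <- cacna1i_variants()
#' nrow(v)  # 10
cacna1i_variants <- function() {
  read_variant_table(system.file("extdata", "cacna1i_variants.tsv",
                                 package = "cav3ephys", mustWork = TRUE))
}

#' Filter variants rare in the control populations
#'
#' Keeps variants whose tested control MAFs are all below `threshold`
#' (rare: < 0.01 by default).
#'
#' @param records A `variant_table` data frame.
#' @param threshold MAF cutoff in (0, 0.5].
#' @param columns Control MAF column(s) to test.
#' @return The retained rows.
#' @export
filter_rare <- function(records, threshold = 0.01,
                        columns = c("gnomad_nfe_maf", "ukbiobank_maf")) {
  if (threshold <= 0 || threshold > 0.5) stop("threshold must be in (0, 0.5]")
  unknown <- setdiff(columns, names(records))
  if (length(unknown) > 0)
    stop("unknown MAF column(s): ", paste(unknown, collapse = ", "))
  keep <- rep(TRUE, nrow(records))
  for (col in columns) keep <- keep & records[[col]] < threshold
  records[keep, , drop = FALSE]
}

round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Aggregate allele counts for the burden comparison
#'
#' Sums estimated alternate-allele counts across variants: per variant the
#' count is `round(MAF * 2N)` (nearest integer, ties away from zero), the
#' same estimation applied to both the case cohort and a control cohort
#' whose individual-level genotypes are summarized by per-variant MAFs.
#' Totals are `2 N V` alleles for `V` variants.
#'
#' @param records A `variant_table` data frame with `case_maf` and the
#'   chosen control column.
#' @param n_case Number of case subjects.
#' @param control_cohort Name of the control MAF column, e.g.
#'   `"ukbiobank_maf"`.
#' @param n_ctrl Number of control subjects.
#' @return A `burden_counts`: list with `case_alt`, `case_total`,
#'   `ctrl_alt`, `ctrl_total`, `n_variants`, `control_cohort`.
#' @export
#' @examples
#' counts <- aggregate_counts(cacna1i_variants(), n_case = 187,
#'                            control_cohort = "ukbiobank_maf",
#'                            n_ctrl = 43000)
#' counts$case_alt  # 17 carriers, all heterozygous
aggregate_counts <- function(records, n_case, control_cohort, n_ctrl) {
  if (n_case <= 0 || n_ctrl <= 0) stop("cohort sizes must be positive")
  if (nrow(records) == 0) stop("no variants to aggregate")
  if (!control_cohort %in% names(records))
    stop("missing control MAF column: ", control_cohort)
  ctrl_maf <- records[[control_cohort]]
  if (any(is.na(ctrl_maf)))
    stop("missing control MAF for ", sum(is.na(ctrl_maf)), " record(s)")
  v <- nrow(records)
  structure(list(
    case_alt = sum(round_half_up(records$case_maf * 2 * n_case)),
    case_total = 2 * n_case * v,
    ctrl_alt = sum(round_half_up(ctrl_maf * 2 * n_ctrl)),
    ctrl_total = 2 * n_ctrl * v,
    n_variants = v, control_cohort = control_cohort
  ), class = "burden_counts")
}

#' Allelic burden test: 2x2 chi-square with odds ratio
#'
#' Compares the aggregated alternate-allele frequency in cases against a
#' control cohort on the 2x2 table (alt/ref x case/control): Pearson
#' chi-square without continuity correction, with the p-value the
#' upper-tail chi-square(1) probability of the statistic, and the odds
#' ratio of the aggregated frequencies. For small cell counts a Fisher
#' exact test (one-sided, increased burden in cases) is available.
#'
#' @param counts A `burden_counts` from [aggregate_counts()].
#' @param method `"chisq"` (default) or `"fisher"`.
#' @return A `burden_result`: list with `case_freq`, `ctrl_freq`,
#'   `odds_ratio`, `chi2` (NA for Fisher), `p_value`, `method`,
#'   `cohort_label`.
#' @export
#' @examples
#' counts <- aggregate_counts(cacna1i_variants(), 187, "ukbiobank_maf", 43000)
#' burden_test(counts)
burden_test <- function(counts, method = c("chisq", "fisher")) {
  method <- match.arg(method)
  if (counts$case_total <= 0 || counts$ctrl_total <= 0)
    stop("allele totals must be positive")
  tab <- matrix(c(counts$case_alt, counts$case_total - counts$case_alt,
                  counts$ctrl_alt, counts$ctrl_total - counts$ctrl_alt),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("case", "ctrl"), c("alt", "ref")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate 2x2 margin; odds ratio undefined")
  f_case <- counts$case_alt / counts$case_total
  f_ctrl <- counts$ctrl_alt / counts$ctrl_total
  or <- (f_case / (1 - f_case)) / (f_ctrl / (1 - f_ctrl))
  if (method == "chisq") {
    ct <- stats::chisq.test(tab, correct = FALSE)
    chi2 <- unname(ct$statistic)
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  } else {
    chi2 <- NA_real_
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
  }
  structure(list(case_freq = f_case, ctrl_freq = f_ctrl, odds_ratio = or,
                 chi2 = chi2, p_value = p, method = method,
                 cohort_label = counts$control_cohort),
            class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf("<burden_result> vs %s: freq %.4f vs %.4f, OR = %.2f, p = %.2g (%s)\n",
              x$cohort_label, x$case_freq, x$ctrl_freq, x$odds_ratio,
              x$p_value, x$method))
  invisible(x)
}
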