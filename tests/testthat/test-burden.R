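test_that("the shipped variant table parses into ten validated records", {
  v <- cacna1i_variants()
  expect_equal(nrow(v), 10L)
  expect_true(all(c("locus", "aa_change", "case_maf", "gnomad_nfe_maf",
                    "ukbiobank_maf") %in% names(v)))
  expect_true(all(v$case_maf >= 0 & v$case_maf <= 0.5))
  # four heterozygous carriers of the most recurrent variant
  expect_equal(v$case_maf[v$aa_change == "p.Q1158H"], 4 / (2 * 187),
               tolerance = 1e-6)
})

test_that("malformed variant tables are rejected with row context", {
  td <- tempfile(fileext = ".tsv")
  writeLines(c("locus\taa_change\tcase_maf\tgnomad_nfe_maf",
               "chr22:1000\tp.A1B\t0.001\t0.0001",
               "chr22:2000\tp.C2D\tabc\t0.0001"), td)
  expect_error(read_variant_table(td), "row\\(s\\) 2")

  writeLines(c("locus\taa_change\tcase_maf\tgnomad_nfe_maf"), td)
  empty <- read_variant_table(td)
  expect_equal(nrow(empty), 0L)

  writeLines(c("locus\tcase_maf", "chr22:1000\t0.001"), td)
  expect_error(read_variant_table(td), "missing required")

  writeLines(c("locus\taa_change\tcase_maf\tgnomad_nfe_maf",
               "chr22:1000\tp.A1B\t0.001\t0.9"), td)
  expect_error(read_variant_table(td), "outside")
})

test_that("rarity filtering tests the control MAF columns", {
  v <- cacna1i_variants()
  # every shipped variant is rare at the 0.01 threshold
  expect_equal(nrow(filter_rare(v)), 10L)
  # a tighter threshold on the gnomAD column keeps only the ultra-rare
  tight <- filter_rare(v, threshold = 0.001, columns = "gnomad_nfe_maf")
  expect_setequal(tight$aa_change,
                  c("p.R111G", "p.M128L", "p.G859C", "p.P905L", "p.R924K"))
  # a common variant is removed
  v2 <- v
  v2$gnomad_nfe_maf[1] <- 0.02
  expect_equal(nrow(filter_rare(v2, columns = "gnomad_nfe_maf")), 9L)
  expect_error(filter_rare(v, columns = "nope_maf"), "unknown MAF")
  expect_error(filter_rare(v, threshold = 0), "threshold")
})

test_that("allele-count aggregation reproduces the case-cohort carriers", {
  v <- cacna1i_variants()
  cnt <- aggregate_counts(v, n_case = 187, control_cohort = "ukbiobank_maf",
                          n_ctrl = 43000)
  expect_equal(cnt$case_alt, 17)           # 17 heterozygous carriers
  expect_equal(cnt$case_total, 2 * 187 * 10)
  expect_equal(cnt$ctrl_total, 2 * 43000 * 10)
  expect_equal(cnt$n_variants, 10L)

  # single-variant sanity: MAF 0.5 in 10 subjects gives 10 of 20 alleles
  one <- v[1, ]
  one$case_maf <- 0.5
  c1 <- aggregate_counts(one, n_case = 10,
                         control_cohort = "ukbiobank_maf", n_ctrl = 10)
  expect_equal(c1$case_alt, 10)
  expect_equal(c1$case_total, 20)

  expect_error(aggregate_counts(v[0, ], 187, "ukbiobank_maf", 43000),
               "no variants")
  expect_error(aggregate_counts(v, 187, "absent_maf", 43000), "missing")

  # unrounded counts: aggregated frequency equals the mean per-variant MAF
  expect_equal(cnt$case_alt / cnt$case_total, mean(v$case_maf),
               tolerance = 2e-3)
})

test_that("the chi-square burden test matches a four-cell oracle", {
  v <- cacna1i_variants()
  cnt <- aggregate_counts(v, 187, "ukbiobank_maf", 43000)
  res <- burden_test(cnt)

  tab <- matrix(c(cnt$case_alt, cnt$case_total - cnt$case_alt,
                  cnt$ctrl_alt, cnt$ctrl_total - cnt$ctrl_alt),
                nrow = 2, byrow = TRUE)
  expect_equal(res$chi2, pearson_chi2_oracle(tab), tolerance = 1e-9)
  expect_equal(res$p_value,
               stats::pchisq(pearson_chi2_oracle(tab), 1,
                             lower.tail = FALSE),
               tolerance = 1e-12)

  # equal frequencies: OR 1, chi2 0
  eq <- structure(list(case_alt = 10, case_total = 1000, ctrl_alt = 100,
                       ctrl_total = 10000, n_variants = 1,
                       control_cohort = "x"), class = "burden_counts")
  req <- burden_test(eq)
  expect_equal(req$odds_ratio, 1.0)
  expect_equal(req$chi2, 0, tolerance = 1e-12)

  # OR invariance under scaling all four cells; chi2 scales linearly
  sc <- structure(list(case_alt = 50, case_total = 5000, ctrl_alt = 100,
                       ctrl_total = 20000, n_variants = 1,
                       control_cohort = "x"), class = "burden_counts")
  sc5 <- sc
  sc5[c("case_alt", "case_total", "ctrl_alt", "ctrl_total")] <-
    lapply(sc[c("case_alt", "case_total", "ctrl_alt", "ctrl_total")],
           function(x) 5 * x)
  class(sc5) <- "burden_counts"
  expect_equal(burden_test(sc5)$odds_ratio, burden_test(sc)$odds_ratio,
               tolerance = 1e-12)
  expect_equal(burden_test(sc5)$chi2, 5 * burden_test(sc)$chi2,
               tolerance = 1e-9)

  # symmetry: swapping case and control inverts the OR, keeps chi2
  sw <- structure(list(case_alt = cnt$ctrl_alt, case_total = cnt$ctrl_total,
                       ctrl_alt = cnt$case_alt, ctrl_total = cnt$case_total,
                       n_variants = cnt$n_variants, control_cohort = "x"),
                  class = "burden_counts")
  rsw <- burden_test(sw)
  expect_equal(rsw$odds_ratio, 1 / res$odds_ratio, tolerance = 1e-12)
  expect_equal(rsw$chi2, res$chi2, tolerance = 1e-9)

  # degenerate margin is flagged
  z <- structure(list(case_alt = 0, case_total = 100, ctrl_alt = 0,
                      ctrl_total = 100, n_variants = 1,
                      control_cohort = "x"), class = "burden_counts")
  expect_error(burden_test(z), "degenerate")

  # Fisher option gives a one-sided exact p of the same order
  rf <- burden_test(cnt, method = "fisher")
  expect_true(is.na(rf$chi2))
  expect_lt(rf$p_value, 0.01)
})
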