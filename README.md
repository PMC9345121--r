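# cav3ephys

Quantitative electrophysiology of Cav3.3 (*CACNA1I*) T-type calcium
channel variants, plus the companion rare-variant burden genetics — as a
tested, fully reproducible R package.

Hemiplegic migraine is a severe migraine subtype; most referred cases are
negative for the three established causal genes, and rare missense
variants in *CACNA1I* (encoding the low-voltage-activated channel Cav3.3)
are candidate contributors. Assessing them takes two kinds of analysis
that this package implements end to end:

1. **Whole-cell voltage-clamp characterization** of wild-type and variant
   channels: current density (pA/pF), voltage dependence of activation and
   steady-state inactivation (SSI), activation/inactivation kinetics,
   window currents, and extracellular pH modulation. Because no raw
   recordings are publicly available for this system, the package includes
   a two-gate Hodgkin–Huxley simulator whose ground truth is the published
   parameter set for six constructs (WT, R111G, M128L, D302G, R307H,
   Q1158H), so every analysis stage can be verified by
   simulate-then-refit.
2. **Rare-variant allelic burden testing**: aggregated alternate-allele
   counts in a 187-proband case cohort versus population controls (gnomAD
   non-Finnish Europeans, UK Biobank) on a 2×2 chi-square with odds ratio.
   The ten-variant case table ships with the package.

It is aimed at ion-channel biophysicists and statistical geneticists who
want a transparent, scriptable reference implementation of these standard
analyses with every number recomputable from a seed.

## The model and statistics

Current model (simulator and kinetics fit):

```
m∞(V) = 1 / (1 + exp((V½ₐ − V)/dₐ))        activation (increasing)
h∞(V) = 1 / (1 + exp((V − V½ᵢ)/dᵢ))        availability (decreasing)
I(t)  = gmax · m(t) · h(t) · (V − Erev)     ohmic, inward below Erev
I(t)  = C (1 − e^(−(t−t₀)/τact)) e^(−(t−t₀)/τinact)   transient fit
```

Gates relax exponentially toward their steady states (exact per-sample
update, no solver error). Fitted G–V and SSI curves use the Boltzmann
forms above; the window current is the area under the pointwise minimum of
the two normalized curves over [−90, +20] mV. The burden statistic is a
Pearson chi-square (no continuity correction) on the alt/ref ×
case/control allele table with upper-tail χ²₁ p-value, and
OR = (f_case/(1−f_case)) / (f_ctrl/(1−f_ctrl)) on aggregated frequencies
f = Σ round(MAF·2N) / 2NV.

## Worked example

```r
library(cav3ephys)

# rare-variant burden: case cohort vs UK Biobank
counts <- aggregate_counts(cacna1i_variants(), n_case = 187,
                           control_cohort = "ukbiobank_maf",
                           n_ctrl = 43000)
burden_test(counts)
#> <burden_result> vs ukbiobank_maf: freq 0.0045 vs 0.0020, OR = 2.32,
#>   p = 0.00038 (chisq)

# simulate a 12-cell WT cohort and refit its activation curve
fx <- cav33_fixtures()
recs <- generate_cohort(fx$WT, protocol_iv(), n_cells = 12, seed = 1)
fits <- analyze_gv(recs)
superplot_summary(fits$v05, fits$replicate_batch,
                  parameter_name = "act V0.5", construct_label = "WT")
#> <superplot_summary> WT act V0.5: -20.573 +/- 0.361 (mean +/- SEM,
#>   n = 12, 3 batch(es))

# window current of WT and the M128L variant
wt <- window_area(list(v05 = -20.6, slope = 5.8),
                  list(v05 = -47.1, slope = 6.9))
wt
#> <window_result> area = 1.4853 mV over [-90, 20] mV (peak at -32.7 mV)
m128l <- window_area(list(v05 = -23.3, slope = 5.1),
                     list(v05 = -45.0, slope = 6.8))
window_ratio(m128l, wt)
#> [1] 1.198826
```

Reading the numbers: the case cohort carries roughly 2.3-fold higher odds
of a rare *CACNA1I* allele than UK Biobank controls; the simulated WT
cohort's fitted half-activation voltage recovers the generating −20.6 mV
within its SEM; and the M128L variant's hyperpolarized, steepened
activation enlarges its window current ~20% relative to WT (directionally
consistent with gain of function).

The end-to-end pipeline — simulate, analyze, compare each variant against
WT, write TSVs and a JSON summary — runs from one call:

```r
run_pipeline(pipeline_config(n_cells = 12, seed = 1), out_dir = "results")
```

A thin command-line wrapper with `simulate`, `analyze`, `burden` and
`report` subcommands is installed at `inst/scripts/cav3ephys.R`.

## Package layout

* `R/` — simulator (`simulate_sweep`, `generate_cohort`), protocols,
  voltage-dependence analysis (`build_gv`, `build_availability`,
  `fit_boltzmann`), kinetics and window currents (`fit_kinetics`,
  `window_area`), pH modulation (`ph_ratios`, `paired_test`,
  `across_construct_test`), burden testing (`read_variant_table`,
  `aggregate_counts`, `burden_test`), cohort statistics and pipeline.
* `inst/extdata/cacna1i_variants.tsv` — the ten-variant case-cohort table.
* `vignettes/cav3ephys-methods.Rmd` — the model, analysis choices,
  numerical details and known limitations.
* `tests/testthat/` — unit, property and end-to-end acceptance tests with
  independent closed-form oracles.
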