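---
title: "Methods: simulated Cav3.3 characterization and burden testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated Cav3.3 characterization and burden testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cav3ephys)
```

## What this package is for

`cav3ephys` characterizes the biophysics of wild-type and
hemiplegic-migraine-associated variants of the T-type calcium channel
Cav3.3 (*CACNA1I*) the way a whole-cell patch-clamp study does, driven by
a synthetic recording generator instead of deposited raw traces (none are
publicly available for this system). The same package implements the
companion genetic analysis: a rare-variant allelic burden test comparing a
case cohort's aggregated alternate-allele counts against population
control databases.

Every analysis stage is therefore verifiable end-to-end: the generator's
ground-truth parameters are known, so the fits, ratios and statistics the
package computes can be checked for recovery, and the burden arithmetic is
checked against the shipped case-cohort variant table.

## The channel model

The current model is a two-gate Hodgkin–Huxley scheme. Activation `m` and
inactivation `h` relax toward voltage-dependent steady states

$$m_\infty(V) = \frac{1}{1 + e^{(V_{0.5,act} - V)/d_{act}}}, \qquad
  h_\infty(V) = \frac{1}{1 + e^{(V - V_{0.5,inact})/d_{inact}}},$$

with positive slope factors $d$ in mV — the increasing/decreasing
orientations that match the measured conductance–voltage and availability
curves. The whole-cell current is ohmic,

$$I(t) = g_{max}\, m(t)\, h(t)\, (V - E_{rev}),$$

in pA for $g_{max}$ in nS and voltages in mV; below the reversal potential
the depolarization-evoked current is inward (negative). Within each
command segment the gates relax as first-order processes with time
constants $\tau_{act}$ and $\tau_{inact}$, integrated *exactly* per sample
(analytic exponential update), so there is no ODE solver and no solver
tolerance. Gaussian noise of configurable standard deviation is added per
sample to emulate recording noise.

Deliberate simplifications:

* **Ohmic driving force** with $E_{rev} = +45$ mV (appropriate for a
  10 mM external Ca^2+^ solution); Goldman–Hodgkin–Katz rectification is
  omitted because every downstream analysis normalizes conductance or
  current, so permeation nonlinearity would only rescale absolute
  amplitudes. Sensitivity: moving $E_{rev}$ by ±10 mV shifts fitted
  activation $V_{0.5}$ by under 1 mV at these test potentials.
* **Voltage-independent time constants within a pulse**: the measured
  $\tau$ values apply at the test potential and are used at all voltages.
  The consequences are discussed under *Known limitations*.
* No cumulative (frequency-dependent) inactivation, no single-channel
  stochasticity, no series-resistance or capacitive artifacts (simulated
  recordings are ideal; the stimulus frequency metadata is carried but has
  no effect).

## Construct panel and ground truth

`cav33_fixtures()` returns the six-construct panel (WT, R111G, M128L,
D302G, R307H, Q1158H) with the measured activation/inactivation Boltzmann
parameters, time constants, and extracellular-pH factors. Two details:

* **Imputed activation slopes.** Activation slope factors were only
  measured for WT (5.8 mV) and M128L (5.1 mV); the other constructs carry
  the WT value and are flagged `act_slope_imputed`.
* **Conductance calibration.** Maximal conductances are not reported
  quantities; each construct's $g_{max}$ is computed at fixture
  construction so the noiseless 100-ms pulse to −10 mV at the reference
  capacitance of 12 pF reproduces the construct's measured current density
  (e.g. 208.4 pA/pF for WT, 104.2 for R307H).

## Stimulation protocols

All protocols hold at −90 mV and sample at 0.1 ms:

| protocol | stimulus | measured quantity |
|---|---|---|
| `protocol_iv()` | 100-ms steps, −90…+60 mV in 5 mV, 0.2 Hz | peak current per step → G–V curve |
| `protocol_ssi()` | 1-s prepulses −90…+20 mV in 5 mV, then 50 ms at −20 mV, 0.1 Hz | test-pulse peak → availability curve |
| `protocol_kinetics()` | 100 ms at 0 mV, 0.1 Hz | rise/decay time constants |
| `protocol_density()` | 100 ms at −10 mV | peak / capacitance |
| `protocol_ph()` | 200-ms pulses at −20 mV, 0.1 Hz, per pH | within-cell peak and τ ratios |

The 5-mV step increment is a choice (the increment is not a reported
quantity); it gives 31-sweep I–V and 23-sweep SSI families, enough to
constrain four-parameter logistic fits comfortably.

## Cell-to-cell variability

`generate_cohort()` emulates biological variability across independent
transfections. Defaults, chosen once to match the between-cell spread
implied by the reported SEMs at the reported cell counts:

* maximal conductance: lognormal around the fixture value, CV 0.30
  (mean-preserving parameterization);
* capacitance: normal 12 ± 3 pF, truncated positive;
* half-maximal voltages (both gates): normal jitter, sd 1.5 mV;
* recording noise: 5 pA sd;
* cells assigned round-robin to three transfection-day batches,
  alternating 24 h / 48 h recording time points.

What this generator does **not** emulate: correlated parameter shifts
within a transfection batch, rundown within a recording session,
seal-quality covariates, leak currents beyond a constant baseline, or any
relationship between capacitance and channel count. Passing
recovery tests therefore demonstrate that the analysis chain is unbiased
under idealized variability, not that it is robust to every failure mode
of real recordings.

## Analysis chain

**Peak currents.** Baseline is the mean current of the holding segment
preceding the pulse; the peak is the signed extremum of the
baseline-subtracted current in the test window. Before peak detection the
window is smoothed with a 0.5-ms running mean — the analysis-side analog
of the low-pass filtering applied to experimental records. Without it,
taking the extremum of ~10^3 white-noise samples systematically inflates
small peaks at the foot of the G–V curve and biases fitted activation
slopes upward by ~0.35 mV; with it the residual bias is ~0.15 mV.
Noiseless oracle comparisons disable the filter.

**G–V and availability curves.** Chord conductance $G = I_{peak}/(V -
E_{rev})$, normalized by the observed maximum over the family (whether the
original analysis normalized by observed or fitted maximum is not stated;
observed is used). Voltages within ±5 mV of $E_{rev}$ are excluded to
avoid division blow-up. Availability is the test-pulse peak normalized by
the family maximum.

**Boltzmann fits.** Orientation-appropriate logistic least squares via
Levenberg–Marquardt (`minpack.lm::nlsLM`), initial guesses from linear
interpolation of the 0.5 crossing and the 0.25–0.75 voltage span
(slope ≈ span / 2 ln 3). Degenerate inputs, trend/orientation mismatch and
optimizer failure set `converged = FALSE` instead of raising; fewer than
five points is an error.

**Kinetics.** The test-pulse transient is fitted with the
exponential-product equation
$I(t) = C\,(1 - e^{-(t-t_0)/\tau_{act}})\,e^{-(t-t_0)/\tau_{inact}}$
(sign-rectified so the transient is positive; $C$ is the y-intercept
scale). Initial guesses: $\tau_{inact}$ from a log-linear regression of
the decay tail, $\tau_{act}$ by inverting the time-to-peak identity
$t_{peak} = \tau_{act} \ln(1 + \tau_{inact}/\tau_{act})$ with `uniroot`,
$t_0$ at the pulse onset. On noiseless traces the data-driven guesses can
be so close to the optimum that the numeric Jacobian degenerates; a
perturbed restart handles that case.

**Window currents.** The tonic-influx band where activation and
availability overlap is quantified as the area under the *pointwise
minimum* of the two fitted normalized curves (the standard window
construction; whether the original computation used the minimum or the
product of the curves is not stated — the minimum is used, and the choice
is isolated behind `window_area()` for sensitivity work). Trapezoid
integration over [−90, +20] mV (the SSI prepulse range) at 0.01 mV; both
bounds and step are arguments. The closed-form check: the two logistics
cross at $V_c = (a\,d_h + b\,d_a)/(d_a + d_h)$ and each side integrates to
a `log1p` expression; quadrature agrees with this closed form to better
than 10^−4^ relative.

**pH modulation.** Each cell is recorded at reference pH 7.4 and one test
pH; the last three sweeps per condition are averaged (a steady-state
block — the transition dynamics between bath conditions are not modeled)
before peak and kinetics measurement. The construct-specific pH factors
are defined as *measured peak-current ratios* at the standard −20 mV
pulse. Consequently `apply_ph()` scales $\tau_{inact}$ by the measured τ
factor and calibrates the conductance scale so the realized peak ratio
equals the measured peak factor: when a pH condition slows inactivation
(Q1158H at pH 8.0, τ factor 1.38), the kinetic slowing by itself enlarges
the transient peak, and scaling $g_{max}$ by the raw factor would
overshoot the measured peak ratio by ~9%. Statistical layer: two-sided
paired t-tests within cells (sidedness is not stated in the source
figures; two-sided is the conservative choice), one-way ANOVA with Tukey
HSD across constructs.

**Cohort statistics.** Per-cell statistics are summarized
replicate-aware: pooled mean ± SEM over all cells (SEM = sd/√n), with
per-batch means for display. The cohort summary of a fitted
parameter is the mean of per-cell fits, not a fit to pooled points,
matching per-cell mean ± SEM reporting. WT-vs-variant comparisons use the
classical equal-variance Student's t-test, two-sided (Welch available by
flag); the original methods name unpaired Student's tests even though one
figure legend mentions a paired test — the unpaired form is adopted and a
paired option exposed. Significance tiers partition (0, 1] with closed
upper bounds: `***` ≤ 0.001 < `**` ≤ 0.01 < `*` ≤ 0.05 < `ns`.

## Burden testing

The variant table ships as a TSV (10 rare heterozygous *CACNA1I* missense
variants confirmed in 187 hemiplegic-migraine probands, with case MAF,
gnomAD non-Finnish-European and UK Biobank MAFs, and pass-through
in-silico predictor columns). The analysis:

1. `filter_rare()` keeps variants with all tested control MAFs < 0.01;
2. `aggregate_counts()` estimates per-variant allele counts as
   round(MAF · 2N) — nearest integer, ties away from zero — and sums them;
   totals are 2NV alleles over V variants. Control sizes default to
   50,000 (gnomAD NFE) and 43,000 (UK Biobank), both configurable;
3. `burden_test()` forms the 2×2 alt/ref × case/control table: Pearson
   chi-square without continuity correction, p-value the upper-tail
   χ²₁ probability (the chi-square test's natural one-sided form, matching
   the a-priori hypothesis of *increased* case burden), odds ratio from
   the aggregated frequencies. A Fisher exact option
   (`method = "fisher"`, one-sided) is available for small counts.

Against the UK Biobank column this reproduces the reported comparison:
17 case alleles, frequencies 0.0045 vs 0.0020, OR 2.32. The reported
gnomAD comparison used a neurological-condition-removed NFE subset whose
per-variant MAFs are not published; it is not reproducible from the
shipped table (which yields a lower OR ≈ 2.05) and the package makes no
attempt to match it.

## Reproducibility design

Every stochastic entry point takes a seed; a pipeline master seed fans out
via `sample.int` in a fixed order into per-(construct, protocol)
sub-seeds, so each cohort is independently reproducible and the pipeline's
JSON summary is byte-identical across runs. Problem sizes used by the
package's own verification: cohorts of 12 cells per construct and
protocol, replicated over three independently seeded cohorts with the
replication-averaged cohort mean compared against the generating value —
averaging across replicates checks estimator bias at a precision (SEM
≈ 0.25 mV for a V₀.₅) that a single 12-cell cohort (SEM ≈ 0.43 mV) cannot;
statistical calibration uses 1,000 null simulations.

## Known limitations

* **Availability floor.** With voltage-independent τ, channels partially
  re-equilibrate toward $h_\infty(-20\,\text{mV})$ (2–5%) during the 50-ms
  SSI test pulse, so the availability curve saturates above zero after
  fully inactivating prepulses. Fitted SSI parameters inherit a small
  depolarizing/shallowing bias — up to +0.65 mV in $V_{0.5}$ and +0.55 mV
  in slope for Q1158H (shallowest SSI, slowest $\tau_{inact}$), under
  +0.35 mV for the other constructs. Real T-type channels recover far more
  slowly at depolarized potentials, so this is a model artifact, not an
  analysis bug.
* **Sustained current at −20 mV.** For the same reason the pH pulse
  carries a small non-decaying component (the window current at −20 mV)
  that the pure product fit cannot represent; the fitted τ ratio for
  Q1158H at pH 8.0 comes out ≈ 1.30 for a generating factor of 1.38.
  Within-construct peak ratios are unaffected.
* **Density estimator tail.** Because per-cell conductance and
  capacitance are drawn independently, per-cell density inherits the
  heavy 1/capacitance tail: small-cohort mean densities scatter widely
  (cohort-to-cohort CV ≈ 17% at n = 17) and sit above the calibration
  target in expectation. Density comparisons across constructs remain
  well-powered (WT vs R307H: p < 0.05 in ≥ 95% of replications at the
  reported cell counts).
* **Window ratios from parameters.** Window areas are computed from
  Boltzmann-fitted curves, not from empirical mean traces; for constructs
  whose activation slope had to be imputed, the resulting
  variant/WT ratios are *not* expected to match ratios derived from
  unpublished empirical curves — they are used directionally (M128L
  enlarged, Q1158H enlarged and depolarized).
* The in-silico pathogenicity columns of the variant table are opaque
  annotations; the package never computes or interprets them.

## Worked example

```{r example, eval = FALSE}
library(cav3ephys)

# burden analysis from the shipped case-cohort table
counts <- aggregate_counts(cacna1i_variants(), n_case = 187,
                           control_cohort = "ukbiobank_maf",
                           n_ctrl = 43000)
burden_test(counts)

# simulate a WT cohort and refit its activation curve
fx <- cav33_fixtures()
recs <- generate_cohort(fx$WT, protocol_iv(), n_cells = 12, seed = 1)
fits <- analyze_gv(recs)
superplot_summary(fits$v05, fits$replicate_batch,
                  parameter_name = "act V0.5", construct_label = "WT")

# window-current ratio of the M128L variant
wt <- window_area(list(v05 = -20.6, slope = 5.8),
                  list(v05 = -47.1, slope = 6.9))
m128l <- window_area(list(v05 = -23.3, slope = 5.1),
                     list(v05 = -45.0, slope = 6.8))
window_ratio(m128l, wt)
```
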