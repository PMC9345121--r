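Package: cav3ephys
Title: Electrophysiological Characterization and Rare-Variant Burden
    Analysis for Cav3.3 Channel Variants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates whole-cell voltage-clamp recordings of T-type
    (Cav3.3) calcium channels with a two-gate Hodgkin-Huxley model and
    analyzes them the way patch-clamp studies do: peak currents and
    current densities, Boltzmann fits of activation and steady-state
    inactivation, exponential-product fits of activation and inactivation
    time constants, window-current areas and variant/wild-type ratios,
    and within-cell extracellular pH modulation with paired and
    across-construct statistics. Also implements a rare-variant allelic
    burden test comparing aggregated alternate-allele counts in a case
    cohort against population control databases via a 2x2 chi-square
    with odds ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
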