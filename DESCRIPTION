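Package: placentapd
Title: Simulation and Pharmacodynamic Analysis of Longitudinal Multimodal
    Placental Imaging Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating and analysing longitudinal multimodal
    imaging studies of placental recovery in preclinical models of
    preeclampsia. Provides a seeded three-arm cohort generator calibrated by
    group trajectory anchors and slopes, forward measurement models for four
    imaging modalities (dual-wavelength photoacoustic oximetry with linear
    spectral unmixing, contrast-enhanced ultrasound bolus time-intensity
    curves with wash-in area-under-curve quantification, pulse-wave Doppler
    resistance-index averaging, and fixed-threshold microvascular flow
    vascular-index mapping), exploratory pharmacodynamic metrics (per-subject
    directionally-adjusted recovery slopes and the Functional Recovery
    Index), and the supporting classical inference (mixed repeated-measures
    ANOVA with Greenhouse-Geisser correction and Bonferroni contrasts,
    homogeneity-of-slopes ANCOVA, one-way ANOVA with Tukey HSD, Pearson
    correlation and simple linear regression), composed into a reproducible
    end-to-end study pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    lhs,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
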