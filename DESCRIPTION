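Package: strokeflow
Title: Arterial Spin Labeling Perfusion Analysis for Chronic Stroke Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of gray-matter cerebral blood flow (CBF) and its
    spatial coefficient of variation (sCoV) from pseudo-continuous arterial
    spin labeling (ASL) control/tag series, together with the cohort-level
    statistics used in chronic-stroke perfusion studies: test-retest
    reliability (single-measure absolute-agreement intraclass correlation,
    within-subject coefficient of variation, Bland-Altman summaries) and
    exercise-training effect analysis (paired tests, time-by-region
    repeated-measures ANOVA with Bonferroni post hocs, paired Hedges' g,
    a random-intercept-and-slope fitness model, and repeated-measures ANOVA
    sample-size calculations via the noncentral F distribution). A digital
    ASL phantom with known ground truth (single-compartment kinetic forward
    model with slice-wise post-label delay, calibrated arterial-transit-time
    dispersion, and lesion and motion-corruption models) makes every pipeline
    stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    lme4,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
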