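# strokeflow

Arterial spin labeling (ASL) perfusion analysis for chronic-stroke cohort
studies: CBF quantification, spatial-CoV transit-time surrogates, test-retest
reliability, and exercise-training effect statistics — all testable end to
end on a built-in digital phantom with known ground truth.

## What it does

Pseudo-continuous ASL measures cerebral blood flow (CBF) by magnetically
labeling arterial blood. From a 4D control/tag series, an M0 reference,
tissue partial-volume maps, a lobar atlas and a lesion mask, `strokeflow`
computes a calibrated CBF map by the single-compartment kinetic model with
slice-wise post-label delay,

    CBF = 6000 · λ · ΔM · exp(PLD_s / T1b)
          ─────────────────────────────────────
          2 · α · T1b · M0 · (1 − exp(−τ / T1b))

and summarizes each session as regional mean GM CBF (ml·100g⁻¹·min⁻¹) and
the spatial coefficient of variation of the GM CBF image (sCoV = 100·SD/mean,
%), an indirect index of arterial transit time. The lesion is always excluded
from GM metrics and assessed separately.

Cohort statistics on top of the imaging metrics:

* **Reliability** — single-measure absolute-agreement ICC(A,1) with
  McGraw–Wong F-based confidence intervals, within-subject CoV, and
  Bland–Altman summaries (mean interscan difference, difference-vs-mean
  correlation, repeatability coefficient 1.96·SD).
* **Training effects** — paired t-tests, time×region repeated-measures
  ANOVA with Bonferroni-adjusted per-lobe post hocs, paired Hedges' g with
  small-sample correction, a random-intercept-and-slope mixed model for
  aerobic fitness with missing follow-ups, and repeated-measures-ANOVA
  sample sizes via the noncentral F distribution.

A digital phantom (`make_ground_truth()`, `simulate_session()`,
`simulate_cohort()`) generates head-shaped sessions with programmed true
CBF, a calibrated arterial-transit-time field, lesions and motion-like gain
spikes, so every stage has an exact ground truth. See the methods vignette
(`vignettes/asl-perfusion-methods.Rmd`) for the model, parameter choices and
limitations.

## Worked example

Simulate the default training cohort (8 subjects, baseline and 6-month
sessions, a +18% parietal-lobe CBF effect programmed into the follow-up
ground truth), quantify every session, and run the effect analysis:

```r
library(strokeflow)
acq <- asl_acquisition(voxel_mm = c(8, 8, 5), n_pairs = 10)
res <- run_training_study(cohort_design("training", seed = 42), acq,
                          shape = c(24, 24, 18))
res$report
#> Training-effect report
#>   global GM CBF: t(7) = 5.94, p = 0.001; g = 1.87 (0.72, 3.01)
#>   global GM sCoV: t(7) = 0.95, p = 0.374; g = 0.30 (-0.41, 1.01)
#>   time x region (CBF): F(3, 21) = 39.88, p = 0.000
#>   per-lobe post hocs (Bonferroni):
#>     frontal   p = 0.7057, p_adj = 1.0000
#>     occipital p = 0.3639, p_adj = 1.0000
#>     parietal  p = 0.0003, p_adj = 0.0014
#>     temporal  p = 0.0283, p_adj = 0.1130
#>   suggested n: CBF 3, sCoV 24
```

The pipeline recovers the programmed effect: only the parietal lobe survives
Bonferroni correction, the time×region interaction is strong, global CBF
rises (the parietal patch lifts the GM mean), and sCoV shows no meaningful
change. The fitness mixed model recovers its generating fixed effects
(baseline ≈ 17.2, +4.9 at 3 months, +3.5 at 6 months ml·kg⁻¹·min⁻¹) from 20
observations including 4 missing 6-month assessments:

```r
res$report$fitness$fixed
#>          term estimate    se     z        p
#> 1 (Intercept)    17.95 1.467 12.23 2.10e-34
#> 2     3-month     4.08 0.818  4.99 6.18e-07
#> 3     6-month     2.79 1.431  1.95 5.17e-02
```

Prospective sample sizes for a definitive trial use the noncentral-F power
method with the repeated-measures convention λ = f²·m·n/(1−ρ):

```r
sample_size_rm_anova(0.27, alpha = 0.05, power = 0.8, rho = 0.5, m = 2)$n
#> [1] 29
```

`run_repeatability_study()` is the analogous one-call driver for the
two-session reliability arm; with an output directory both drivers write
metrics/report CSVs, per-subject NIfTI maps (training) and a YAML echo of
every constant used.

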