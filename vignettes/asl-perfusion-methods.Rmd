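---
title: "Methods: ASL perfusion quantification, its digital phantom, and the cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ASL perfusion quantification, its digital phantom, and the cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokeflow)
```

## What the package computes

`strokeflow` analyzes pseudo-continuous arterial spin labeling (pCASL) MRI in
chronic-stroke cohorts. From a 4D control/tag series, a proton-density (M0)
reference, tissue partial-volume maps, a lobar atlas and a lesion mask, it
produces a calibrated cerebral blood flow (CBF) map and two scalar summaries
per region: mean gray-matter (GM) CBF (ml·100g⁻¹·min⁻¹) and the spatial
coefficient of variation of the GM CBF image (sCoV, %), a heuristic index of
arterial transit time (ATT). On top of the imaging metrics it implements the
cohort statistics such studies report: test-retest reliability of the two
metrics, and the effect analysis of a baseline/6-month exercise-training
design.

Because no patient data ship with the package, every stage is exercised on a
digital phantom with known ground truth: the phantom defines what "correct"
means, and the test suite checks the pipeline against it.

## The kinetic model

Quantification follows the single-compartment model used with consensus
constants. For a voxel in slice $s$ of an ascending 2D readout, the
control−tag difference $\Delta M$ relates to perfusion $f$ by

$$
\Delta M = \frac{2\,\alpha\,M_0\,f\,T_{1b}\,
  \bigl(1-e^{-\tau/T_{1b}}\bigr)\,e^{-\mathrm{PLD}_s/T_{1b}}}{6000\,\lambda},
\qquad \mathrm{PLD}_s = \mathrm{PLD}_0 + (s-1)\,\Delta t_s ,
$$

with $\tau$ the label duration, $\alpha$ the labeling efficiency, $T_{1b}$
the T1 of arterial blood and $\lambda$ the blood–brain partition
coefficient. `quantify_cbf()` inverts this voxelwise, slice by slice.
Defaults: $\tau = 1650$ ms, $\mathrm{PLD}_0 = 1600$ ms, 18 slices, 30
control/tag pairs, $\alpha = 0.85$, $T_{1b} = 1650$ ms, $\lambda = 0.9$
ml/g, 5-mm smoothing FWHM. The per-slice PLD increment of a 2D echo-planar
readout is rarely reported; the default $\Delta t_s = 35$ ms is a typical
slice readout time, is configurable, and is echoed in every run
configuration.

Pipeline order (`run_session()`): difference series → SNR-optimizing volume
selection → average retained pairs → spatial smoothing → kinetic inversion →
GM masking (partial volume ≥ 0.5, lesion always excluded) → regional
metrics. Whether smoothing is better applied to the mean difference image or
to the CBF map is not settled; the default smooths the difference image and
a flag (`smooth_before_quantify = FALSE`) flips the order for sensitivity
analyses.

Numerical choices worth knowing:

* negative CBF voxels are **retained** in means and sCoV — clipping would
  bias low-SNR means upward;
* sCoV uses the sample (n−1) standard deviation;
* voxels with M0 below 10% of the robust (90th-percentile) brain M0 are set
  undefined and excluded, preventing division blow-ups at mask edges;
* control−tag is taken positive; `sign_flip` accommodates the opposite
  vendor convention.

### Volume selection

Motion-degraded ASL volumes are handled by a greedy SNR optimization
(`select_volumes()`): volumes are ranked by agreement with the voxelwise
median difference volume over GM, and the prefix maximizing GM SNR of the
running mean is retained (never fewer than max(2, 20%) of the volumes).
Agreement is Lin's concordance correlation rather than Pearson correlation:
the corruption the phantom models — whole-volume gain spikes — rescales a
volume without changing its Pearson correlation with the median, so only a
scale- and shift-sensitive index can rank corrupted volumes last. The exact
algorithm of the published SNR-optimization strategy this stands in for is
not public; ours is a documented, tested surrogate.

## The digital phantom

`make_ground_truth()` builds, on a regular grid, an ellipsoidal brain with a
CSF rim, a GM shell partitioned into four lobes (frontal, occipital,
parietal, temporal), a WM core, a central 2×2-voxel arterial column, and an
optional spherical lesion (default volume ≈ 0.4% of brain, true CBF halved).
The ellipsoid's z semi-axis deliberately exceeds the slice stack, as an ASL
field of view crops the head; this also keeps the arterial column inside
white matter on every slice. Partial-volume maps are crisp (0/1), which
makes mask geometry exactly countable in tests. True WM CBF is 0.4 × the
subject's GM CBF and CSF is 0 — the analysis itself only reads GM. M0 tissue
weights are GM 1.0, WM 0.75, CSF 1.3 (× 1000 raw units); their exact values
are immaterial because quantification divides by the measured M0.

`simulate_session()` runs the kinetic model forward. Voxels whose ATT
exceeds the slice PLD deliver only the fraction
$\max(0, 1 - (\mathrm{ATT}-\mathrm{PLD}_s)/\tau)$ of their label; the
undelivered mass is re-deposited into the slice's arterial voxels, so total
label per slice is conserved — the mechanism by which prolonged transit
times raise sCoV while macrovascular signal persists. Noise is additive
Gaussian, identical on control and tag (difference images are approximately
Gaussian; Rician floor effects are out of scope). Motion is modeled as
whole-volume multiplicative gain spikes rather than geometric transforms,
because registration is out of scope and gain spikes are exactly what the
volume-exclusion logic must catch.

### ATT calibration

The ATT field is 1200 ms plus a spatially smooth Gaussian random field. Its
dispersion is *calibrated*: with spatially uniform true CBF, the sCoV of the
measured map equals the spatial CoV of the delivery fraction, whose first
two moments under the Gaussian ATT marginal are computed by numerical
integration over the slice-PLD mixture (weighted by per-slice GM voxel
counts) and inverted with `uniroot()` (`att_sd_for_scov()`). Subject sCoV
targets are drawn from N(45, 12²)% in the repeatability design and clamped
to at most 85%, since the delivery-fraction CoV approaches 100% only
asymptotically. The cohort's true ATT distribution is a modeling choice, not
a reconstruction — only its sCoV consequence is used downstream.

One consequence to keep in mind: generating a 45% sCoV purely by
under-delivery means the mean delivery fraction is ≈ 0.75, so *measured* GM
CBF sits ≈ 25% below the programmed true CBF at default settings. True CBF
is programmed at N(51, 15²) (repeatability) and N(40, 13²) (training)
ml·100g⁻¹·min⁻¹; reliability statistics are unaffected because they are
invariant to that common scale factor.

### Cohorts

* **Repeatability** (n = 12, two sessions): the second session perturbs the
  subject's global true CBF by N(0, 7²) ml·100g⁻¹·min⁻¹ — chosen between the
  value implied by the published within-subject CoV (≈ 6.8) and by the
  published ICC (≈ 9.1) — while the ATT field, being anatomy, stays fixed
  within subject.
* **Training** (n = 8, baseline/6-month): follow-up true CBF is multiplied
  per lobe by 1 + effect/100 exactly; the default effect is parietal +18%
  with the other lobes null, isolating the regional effect the design is
  meant to detect. The observed cohort also showed a ~15% global rise with
  non-significant trends elsewhere; the phantom default deliberately does
  not emulate between-subject response heterogeneity (the ±12% spread), so
  recovered changes are tighter than real ones. A small mechanical sCoV
  shift accompanies any regional CBF patch (it adds spatial variance), which
  real data at n = 8 would not resolve.
* **Fitness**: V̇O₂peak follows a random-intercept-and-slope model with
  fixed effects matching baseline/3-month/6-month means of 17.2/22.1/20.7
  ml·kg⁻¹·min⁻¹ (so the 3- and 6-month contrasts are +4.9 and +3.5),
  SD(intercept) = 5, SD(slope) = 0.2/month, SD(residual) = 1.5 — variance
  components are plausible inventions. Half the subjects (4 of 8) lack the
  6-month assessment; baseline rows are never removed.

## Statistics

* **ICC(A,1)** (`icc_absolute_single()`): two-way ANOVA decomposition,
  absolute agreement, single measurement, with the McGraw–Wong F-based 95%
  CI (formulas in the function documentation). A constant matrix is flagged
  undefined rather than silently returning a number.
* **Within-subject CoV**: $s_w = \sqrt{\sum d_i^2 / 2n}$ over the grand
  mean; its CI uses the root-formula approximation
  $\mathrm{wsCoV}\,(1 \pm 1.96/\sqrt{2n})$ and is reported as approximate —
  the originating study does not state its CI method, and printed intervals
  cannot adjudicate between variants without raw data.
* **Bland–Altman**: mean interscan difference, Pearson correlation of
  difference vs mean (the study reports parametric r/p), and repeatability
  coefficient 1.96 × SD(d) (the SD-based variant, not 2.77 sw; they differ
  only through the mean-difference term).
* **RM-ANOVA** (`rm_anova_interaction()`): univariate within-subject ANOVA
  via `stats::aov()` error strata; the time×region interaction is tested
  against the subject×time×region stratum, df1 = 3, df2 = 3(n−1). No
  sphericity correction by default (time has 2 levels); Greenhouse–Geisser
  is available by flag. The test suite checks the F ratios against an
  independent brute-force sums-of-squares decomposition.
* **Hedges' g for paired samples**: standardizer = SD of difference scores
  (the cited paired-samples definition; the occasion-SD average is available
  behind a flag), small-sample factor $J = 1 - 3/(4(n-1)-1)$, normal
  approximate CI with $\mathrm{Var}(g) \approx 1/n + g^2/2n$.
* **Fitness LMM** (`fit_fitness_lmm()`): `lme4::lmer` by maximum
  likelihood, all available rows, Wald z per contrast — the simplest
  defensible inference at n = 8, reported as approximate; singular
  random-effect fits are refit with a random intercept only and the
  structure used is recorded. The exact multiple-contrast adjustment behind
  published significance stars is unstated in such reports; Wald z per
  contrast is the documented stand-in.
* **Sample size** (`sample_size_rm_anova()`): smallest n whose noncentral-F
  power, with df1 = m−1, df2 = (n−1)(m−1) and
  $\lambda = f^2 m n/(1-\rho)$, reaches the target. The effect-size
  convention sets f equal to the paired |g| directly (not |g|/2); under this
  convention the published design pair (f = 0.27 → n = 29, f = 0.15 → n =
  90 at α = 0.05, power 0.8, ρ = 0.5, m = 2) is reproduced exactly, which
  is how the convention was fixed.
* Significance is two-sided at 0.05 throughout; lobar post hocs use
  Bonferroni (×4, capped at 1).

## Problem sizes used by the test suite

Simulation-backed checks run at the package's replicate-study scale, chosen
so the whole suite stays comfortably interactive while estimates remain
well-resolved:

* default single studies: 40×40×18 grid (4.8×4.8×5 mm voxels, preserving
  the 192-mm in-plane field of view), 30 pairs;
* replicate studies (100 training cohorts for effect recovery): 24×24×18
  grid with 8-mm in-plane voxels and 10 pairs;
* metric-level calibration: 100 cohorts for ICC interval coverage, 500 null
  cohorts for the lobar type-I rate, 100 cohorts for fitness fixed-effect
  recovery.

## What passing tests do and do not show

The phantom is geometric, not anatomical: crisp tissue boundaries, uniform
true CBF within GM, Gaussian noise, gain-spike "motion". Passing tests
demonstrate that the implementation inverts its own forward physics exactly,
that the statistics match independent oracles and their programmed
ground-truth parameters, and that the published desk-recomputable numbers
(sample sizes, percent changes) are reproduced. They do not certify
performance on real data — partial-volume bias, registration error, Rician
noise, physiological drift and real ATT topography are all outside the
phantom. Known limitations beyond that: no partial-volume correction of CBF
values, no multi-PLD ATT fitting, no voxelwise inference, and the
repeatability of sCoV in the phantom is driven almost entirely by
between-subject variation because within-subject vascular anatomy is held
fixed.
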