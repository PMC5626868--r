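#' Cohort design for the digital ASL phantom
#'
#' Parameterizes the two study arms the phantom emulates: a repeatability arm
#' (two scans about one month apart) and a training arm (baseline and 6-month
#' scans around an exercise rehabilitation program, with a three-timepoint
#' aerobic-fitness record).
#'
#' Defaults encode the study conditions: repeatability n = 12 with global GM
#' CBF drawn from N(51, 15^2) ml/100g/min and subject sCoV targets from
#' N(45, 12^2) percent; training n = 8 with baseline CBF from N(40, 13^2),
#' a +18 percent parietal-lobe effect applied exactly at follow-up, and a
#' fitness generator whose fixed effects match baseline/3-month/6-month peak
#' oxygen uptake means of 17.2, 22.1 and 20.7 ml/kg/min, with 4 of 8 subjects
#' missing the 6-month assessment.
#'
#' @param design_kind `"repeatability"` or `"training"`.
#' @param n_subjects Number of subjects.
#' @param mean_gm_cbf,sd_gm_cbf Population mean/SD of true subject-level GM
#'   CBF (ml/100g/min); subject draws are truncated at 5.
#' @param scov_target_pct Target spatial CoV of the GM CBF image, percent.
#'   Either a scalar (all subjects identical) or length-2 `c(mean, sd)` for a
#'   truncated-normal subject draw (floor 5).
#' @param within_session_noise_sd Thermal noise SD, raw signal units, i.i.d.
#'   Gaussian per voxel per volume.
#' @param between_session_sd Session-to-session SD of true subject GM CBF
#'   (repeatability arm), ml/100g/min.
#' @param regional_effect_pct Named numeric, multiplicative percent change of
#'   follow-up GM CBF per lobe (training arm); must name exactly
#'   `frontal`, `occipital`, `parietal`, `temporal`.
#' @param fitness_params List with elements `beta0`, `beta_3m`, `beta_6m`
#'   (fixed effects, ml/kg/min), `sd_intercept`, `sd_slope` (per month),
#'   `sd_resid` (random-effect and residual SDs) and `n_missing_6m`
#'   (subjects without a 6-month record; baseline is never removed).
#' @param lesion_radius_vox Lesion sphere radius in voxels; `NULL` sizes the
#'   lesion to about 0.4 percent of brain volume; `0` disables it.
#' @param seed Integer base seed; all phantom randomness derives from it.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(design_kind = c("repeatability", "training"),
                          n_subjects = NULL,
                          mean_gm_cbf = NULL, sd_gm_cbf = NULL,
                          scov_target_pct = NULL,
                          within_session_noise_sd = 1.5,
                          between_session_sd = NULL,
                          regional_effect_pct = NULL,
                          fitness_params = NULL,
                          lesion_radius_vox = NULL,
                          seed = 1L) {
  design_kind <- match.arg(design_kind)
  if (design_kind == "repeatability") {
    if (is.null(n_subjects)) n_subjects <- 12L
    if (is.null(mean_gm_cbf)) mean_gm_cbf <- 51
    if (is.null(sd_gm_cbf)) sd_gm_cbf <- 15
    if (is.null(scov_target_pct)) scov_target_pct <- c(45, 12)
    if (is.null(between_session_sd)) between_session_sd <- 7
    regional_effect_pct <- NULL
    fitness_params <- NULL
  } else {
    if (is.null(n_subjects)) n_subjects <- 8L
    if (is.null(mean_gm_cbf)) mean_gm_cbf <- 40
    if (is.null(sd_gm_cbf)) sd_gm_cbf <- 13
    if (is.null(scov_target_pct)) scov_target_pct <- c(50, 20)
    if (is.null(between_session_sd)) between_session_sd <- 0
    if (is.null(regional_effect_pct)) {
      regional_effect_pct <- c(frontal = 0, occipital = 0,
                               parietal = 18, temporal = 0)
    }
    if (is.null(fitness_params)) fitness_params <- list()
    fp_def <- list(beta0 = 17.2, beta_3m = 4.9, beta_6m = 3.5,
                   sd_intercept = 5, sd_slope = 0.2, sd_resid = 1.5,
                   n_missing_6m = min(4L, as.integer(n_subjects) %/% 2L))
    fitness_params <- utils::modifyList(fp_def, fitness_params)
  }
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (sd_gm_cbf < 0 || within_session_noise_sd < 0 || between_session_sd < 0)
    stop("standard deviations must be >= 0")
  if (!length(scov_target_pct) %in% c(1L, 2L) || any(scov_target_pct < 0))
    stop("scov_target_pct must be a nonnegative scalar or c(mean, sd)")
  if (!is.null(regional_effect_pct)) {
    lobes <- c("frontal", "occipital", "parietal", "temporal")
    if (!setequal(names(regional_effect_pct), lobes))
      stop("regional_effect_pct must be named for exactly the 4 lobes: ",
           paste(lobes, collapse = ", "))
    regional_effect_pct <- regional_effect_pct[lobes]
  }
  if (!is.null(fitness_params)) {
    with(fitness_params, stopifnot(sd_intercept >= 0, sd_slope >= 0,
                                   sd_resid >= 0, n_missing_6m >= 0,
                                   n_missing_6m <= n_subjects))
  }
  structure(list(
    design_kind = design_kind, n_subjects = as.integer(n_subjects),
    mean_gm_cbf = mean_gm_cbf, sd_gm_cbf = sd_gm_cbf,
    scov_target_pct = scov_target_pct,
    within_session_noise_sd = within_session_noise_sd,
    between_session_sd = between_session_sd,
    regional_effect_pct = regional_effect_pct,
    fitness_params = fitness_params,
    lesion_radius_vox = lesion_radius_vox,
    seed = as.integer(seed)
  ), class = "cohort_design")
}

# Deterministic per-subject seed, kept well below 2^31.
subject_seed <- function(seed, subject_index, salt = 0L) {
  (as.integer(seed) %% 100000L) * 10000L + as.integer(subject_index) * 10L +
    as.integer(salt)
}

#' Mean and SD of the label delivery fraction under a Gaussian ATT marginal
#'
#' The phantom delivers the full label to a voxel when its arterial transit
#' time (ATT) is at most the slice PLD, and a fraction
#' `max(0, 1 - (ATT - PLD)/tau)` otherwise. With ATT ~ N(base, sd^2) this
#' computes the first two moments of the delivery fraction across a mixture
#' of slice PLDs, by adaptive quadrature. The spatial CoV of a measured CBF
#' map with uniform true CBF equals the CoV of this delivery fraction.
#'
#' @param att_sd_ms ATT dispersion, ms.
#' @param plds_ms Slice PLD schedule, ms.
#' @param weights Mixture weights per slice (e.g. GM voxel counts).
#' @param att_base_ms Mean ATT, ms.
#' @param tau_ms Label duration, ms.
#' @return List with `mean`, `sd` and `cov_pct` of the delivery fraction.
#' @keywords internal
delivery_moments <- function(att_sd_ms, plds_ms, weights = NULL,
                             att_base_ms = 1200, tau_ms = 1650) {
  if (is.null(weights)) weights <- rep(1, length(plds_ms))
  weights <- weights / sum(weights)
  if (att_sd_ms <= 0) return(list(mean = 1, sd = 0, cov_pct = 0))
  m1 <- m2 <- 0
  for (i in seq_along(plds_ms)) {
    pld <- plds_ms[i]
    f <- function(a) pmin(1, pmax(0, 1 - (a - pld) / tau_ms))
    dens <- function(a) stats::dnorm(a, att_base_ms, att_sd_ms)
    lo <- att_base_ms - 8 * att_sd_ms
    hi <- att_base_ms + 8 * att_sd_ms
    m1 <- m1 + weights[i] *
      stats::integrate(function(a) f(a) * dens(a), lo, hi,
                       subdivisions = 500L)$value
    m2 <- m2 + weights[i] *
      stats::integrate(function(a) f(a)^2 * dens(a), lo, hi,
                       subdivisions = 500L)$value
  }
  v <- max(0, m2 - m1^2)
  list(mean = m1, sd = sqrt(v), cov_pct = 100 * sqrt(v) / m1)
}

#' Calibrate ATT dispersion to a target spatial CoV
#'
#' Inverts [delivery_moments()] over the ATT dispersion so that the spatial
#' CoV of the delivery fraction — and hence of a measured CBF map with
#' spatially uniform true CBF — matches `scov_target_pct`.
#'
#' @inheritParams delivery_moments
#' @param scov_target_pct Target spatial CoV, percent.
#' @return ATT dispersion in ms.
#' @export
att_sd_for_scov <- function(scov_target_pct, plds_ms, weights = NULL,
                            att_base_ms = 1200, tau_ms = 1650) {
  if (scov_target_pct <= 0) return(0)
  g <- function(s) delivery_moments(s, plds_ms, weights,
                                    att_base_ms, tau_ms)$cov_pct -
    scov_target_pct
  hi <- 500
  while (g(hi) < 0 && hi < 64000) hi <- hi * 2
  if (g(hi) < 0)
    stop("scov_target_pct = ", scov_target_pct,
         "% is not attainable by ATT dispersion alone")
  stats::uniroot(g, c(1e-6, hi), tol = 1e-3)$root
}

# Smooth standardized Gaussian random field over a mask: white noise smoothed
# with a fixed 1.5-voxel sigma, then standardized to mean 0 / SD 1 over the
# mask so the marginal SD can be set exactly by rescaling.
make_smooth_field <- function(shape, mask, seed) {
  set.seed(seed)
  w <- array(stats::rnorm(prod(shape)), dim = shape)
  f <- gaussian_smooth3d(w, sigma_vox = c(1.5, 1.5, 1.5))
  mu <- mean(f[mask]); s <- stats::sd(f[mask])
  (f - mu) / s
}

#' Generate the ground-truth phantom for one subject
#'
#' Builds a head-shaped digital phantom on a regular grid: an ellipsoidal
#' brain with a CSF rim, a gray-matter (GM) shell partitioned into four
#' non-overlapping lobes (frontal, occipital, parietal, temporal), and a
#' white-matter core holding a small arterial (macrovascular) column. The
#' subject's true GM CBF is drawn from the design's population distribution
#' (truncated at 5 ml/100g/min); WM CBF is 0.4 of GM CBF and CSF 0. The ATT
#' field is a base of 1200 ms plus a spatially smooth Gaussian random field
#' whose dispersion is calibrated so the downstream spatial CoV matches the
#' subject's target. An optional spherical ischemic lesion reduces local true
#' CBF to half of its surroundings.
#'
#' Deterministic given `(seed, subject_index)`.
#'
#' @param shape Integer length-3 grid dimensions; at least 16 x 16 x 8.
#' @param design A [cohort_design()].
#' @param subject_index 1-based subject index.
#' @param seed Integer seed (defaults to the design's).
#' @param acq An [asl_acquisition()]; only its slice PLD schedule and label
#'   duration enter, through the sCoV calibration. Its `n_slices` must match
#'   `shape[3]`.
#' @return An object of class `asl_truth`: arrays `cbf_true` (ml/100g/min),
#'   `att_true` (ms), `pv_gm`, `pv_wm`, `pv_csf`, integer `lobe_atlas`
#'   (0 none, 1 frontal, 2 occipital, 3 parietal, 4 temporal), logical
#'   `arterial_mask`, `lesion_mask`, `brain_mask`, plus scalars
#'   `cbf_gm` (subject-level true GM CBF), `scov_target_pct`, `att_sd_ms`,
#'   `att_base_ms`.
#' @export
make_ground_truth <- function(shape, design, subject_index = 1L,
                              seed = design$seed,
                              acq = asl_acquisition(n_slices = shape[3])) {
  stopifnot(inherits(design, "cohort_design"))
  shape <- as.integer(shape)
  if (length(shape) != 3 || shape[1] < 16 || shape[2] < 16 || shape[3] < 8)
    stop("grid too small to place the four lobar shells; ",
         "minimum shape is 16 x 16 x 8 voxels")
  if (acq$n_slices != shape[3])
    stop("acq$n_slices (", acq$n_slices, ") must equal shape[3] (",
         shape[3], ")")
  set.seed(subject_seed(seed, subject_index, salt = 0L))

  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  # the z semi-axis exceeds the grid: the ellipsoid is cropped by the slice
  # stack, as an ASL field of view crops the head, and the central arterial
  # column stays inside the white-matter core on every slice
  ax <- 0.45 * nx; ay <- 0.45 * ny; az <- 0.75 * nz
  xs <- (seq_len(nx) - cx) / ax
  ys <- (seq_len(ny) - cy) / ay
  zs <- (seq_len(nz) - cz) / az
  X <- array(rep(xs, times = ny * nz), dim = shape)
  Y <- array(rep(rep(ys, each = nx), times = nz), dim = shape)
  Z <- array(rep(zs, each = nx * ny), dim = shape)
  r <- sqrt(X^2 + Y^2 + Z^2)

  brain <- r <= 1
  csf <- r > 0.92 & brain
  gm <- r > 0.70 & r <= 0.92
  wm <- r <= 0.70

  pv_gm <- array(0, shape); pv_gm[gm] <- 1
  pv_wm <- array(0, shape); pv_wm[wm] <- 1
  pv_csf <- array(0, shape); pv_csf[csf] <- 1

  # lobe partition of the GM shell: superior cap = parietal, inferior cap =
  # temporal, remaining belt split anterior (frontal) / posterior (occipital)
  zn <- Z / pmax(r, 1e-9)
  atlas <- array(0L, shape)
  atlas[gm & zn > 0.45] <- 3L
  atlas[gm & zn < -0.45] <- 4L
  belt <- gm & atlas == 0L
  atlas[belt & Y > 0] <- 1L
  atlas[belt & Y <= 0] <- 2L
  for (k in 1:4) if (!any(atlas == k))
    stop("lobe ", k, " is empty; enlarge the grid")

  # arterial column: 2x2 voxels at the grid center through all brain slices
  arterial <- array(FALSE, shape)
  ix <- floor(cx) + 0:1; iy <- floor(cy) + 0:1
  for (s in seq_len(nz)) {
    sl <- brain[ix, iy, s]
    if (any(sl)) arterial[ix, iy, s] <- sl
  }

  # subject-level draws
  cbf_gm <- max(5, stats::rnorm(1, design$mean_gm_cbf, design$sd_gm_cbf))
  scov <- design$scov_target_pct
  scov_t <- if (length(scov) == 2) max(5, stats::rnorm(1, scov[1], scov[2]))
            else scov[1]
  # delivery-fraction CoV approaches 100% only asymptotically in the ATT
  # dispersion; clamp subject draws to the comfortably attainable range
  scov_t <- min(scov_t, 85)

  cbf <- array(0, shape)
  cbf[gm] <- cbf_gm
  cbf[wm] <- 0.4 * cbf_gm

  # lesion: sphere centered on a GM voxel, true CBF halved
  lesion <- array(FALSE, shape)
  radius <- design$lesion_radius_vox
  if (is.null(radius))
    radius <- (0.004 * sum(brain) * 3 / (4 * pi))^(1 / 3)
  if (radius > 0) {
    cand <- which(gm & abs(zn) < 0.45)
    ctr <- arrayInd(cand[sample.int(length(cand), 1)], shape)
    I <- array(rep(seq_len(nx), times = ny * nz), dim = shape)
    J <- array(rep(rep(seq_len(ny), each = nx), times = nz), dim = shape)
    K <- array(rep(seq_len(nz), each = nx * ny), dim = shape)
    lesion <- ((I - ctr[1])^2 + (J - ctr[2])^2 + (K - ctr[3])^2) <= radius^2 &
      brain
    cbf[lesion] <- 0.5 * cbf[lesion]
  }

  # ATT: base + smooth field scaled to the dispersion matching the sCoV target
  plds <- slice_plds(acq)
  wts <- vapply(seq_len(nz), function(s) sum(gm[, , s]), numeric(1))
  att_base <- 1200
  att_sd <- att_sd_for_scov(scov_t, plds, wts, att_base, acq$tau_label_ms)
  field <- make_smooth_field(shape, brain,
                             subject_seed(seed, subject_index, salt = 1L))
  att <- pmax(att_base + att_sd * field, 100)
  att[!brain] <- att_base

  structure(list(
    cbf_true = cbf, att_true = att,
    pv_gm = pv_gm, pv_wm = pv_wm, pv_csf = pv_csf,
    lobe_atlas = atlas, arterial_mask = arterial, lesion_mask = lesion,
    brain_mask = brain,
    cbf_gm = cbf_gm, scov_target_pct = scov_t,
    att_sd_ms = att_sd, att_base_ms = att_base
  ), class = "asl_truth")
}

# Session variant of a subject's truth: same anatomy and lesion, true CBF
# rescaled to new_cbf_gm (preserving WM/lesion ratios), ATT field re-realized
# at the same calibrated dispersion.
session_truth <- function(truth, new_cbf_gm = truth$cbf_gm, field_seed = NULL,
                          lobe_factor = NULL) {
  out <- truth
  out$cbf_true <- truth$cbf_true * (new_cbf_gm / truth$cbf_gm)
  out$cbf_gm <- new_cbf_gm
  if (!is.null(lobe_factor)) {
    for (k in 1:4) {
      idx <- truth$lobe_atlas == k & !truth$lesion_mask
      out$cbf_true[idx] <- out$cbf_true[idx] * lobe_factor[k]
    }
  }
  if (!is.null(field_seed)) {
    field <- make_smooth_field(dim(truth$cbf_true), truth$brain_mask,
                               field_seed)
    att <- pmax(truth$att_base_ms + truth$att_sd_ms * field, 100)
    att[!truth$brain_mask] <- truth$att_base_ms
    out$att_true <- att
  }
  out
}

#' Simulate one ASL session from ground truth
#'
#' Forward model of the single-compartment kinetic equation with slice-wise
#' PLD. The equilibrium signal is tissue-weighted
#' (`m0 = 1000 * (1.0 pv_gm + 0.75 pv_wm + 1.3 pv_csf)`). For a voxel in
#' slice `s` with ATT at most the slice PLD, the control-minus-tag difference
#' is
#' \deqn{\Delta M = \frac{2\,\alpha\, M_0\, f\, T_{1b}
#'   (1 - e^{-\tau/T_{1b}})\, e^{-PLD_s/T_{1b}}}{6000\,\lambda}}
#' with `f` the true CBF in ml/100g/min and times in seconds inside the
#' exponentials. Voxels with ATT beyond the slice PLD deliver only the
#' fraction `max(0, 1 - (ATT - PLD_s)/tau)`; the undelivered label mass of
#' each slice is re-deposited into that slice's arterial (macrovascular)
#' voxels, conserving total label per slice. Control and tag volumes are the
#' M0-proportional baseline plus/minus half the difference signal, with
#' i.i.d. Gaussian noise per voxel per volume. Optional whole-volume gain
#' spikes on selected pairs emulate motion-corrupted volumes.
#'
#' @param truth An `asl_truth` phantom.
#' @param acq An [asl_acquisition()] whose `n_slices` matches the grid.
#' @param noise_sd Thermal noise SD in raw signal units (>= 0).
#' @param seed Integer seed; output is deterministic given it.
#' @param corrupt_pairs Integer indices of pairs to corrupt (default none).
#' @param corrupt_gain Multiplicative gain applied to corrupted volumes.
#' @return An object of class `asl_dataset`: 4D `control` and `tag`
#'   (x, y, z, pair), 3D `m0`, the `acq`, the `truth`, and
#'   `subject_id`/`session_id` fields.
#' @export
simulate_session <- function(truth, acq, noise_sd = 0, seed = 1L,
                             corrupt_pairs = integer(0), corrupt_gain = 5) {
  stopifnot(inherits(truth, "asl_truth"), inherits(acq, "asl_acq"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  shape <- dim(truth$cbf_true)
  if (acq$n_slices != shape[3])
    stop("acq$n_slices must equal the phantom's third dimension")
  set.seed(seed)

  m0 <- 1000 * (truth$pv_gm + 0.75 * truth$pv_wm + 1.3 * truth$pv_csf)
  dm <- delta_m_forward(truth, acq, m0)

  n <- acq$n_pairs
  control <- array(0, c(shape, n))
  tag <- array(0, c(shape, n))
  nv <- prod(shape)
  for (i in seq_len(n)) {
    eps_c <- if (noise_sd > 0) stats::rnorm(nv, 0, noise_sd) else 0
    eps_t <- if (noise_sd > 0) stats::rnorm(nv, 0, noise_sd) else 0
    cv <- m0 + dm / 2 + eps_c
    tv <- m0 - dm / 2 + eps_t
    if (i %in% corrupt_pairs) {
      cv <- cv * corrupt_gain
      tv <- tv * corrupt_gain
    }
    control[, , , i] <- cv
    tag[, , , i] <- tv
  }
  structure(list(control = control, tag = tag, m0 = m0, acq = acq,
                 truth = truth, subject_id = NA_character_,
                 session_id = NA_integer_),
            class = "asl_dataset")
}

# Noiseless forward difference signal, including slice-wise label-mass
# re-deposition of undelivered label into arterial voxels.
delta_m_forward <- function(truth, acq, m0) {
  shape <- dim(truth$cbf_true)
  t1b <- acq$t1_blood_ms / 1000
  tau <- acq$tau_label_ms / 1000
  plds <- slice_plds(acq) / 1000
  dm <- array(0, shape)
  for (s in seq_len(shape[3])) {
    full <- (2 * acq$alpha_eff * m0[, , s] * truth$cbf_true[, , s] * t1b *
               (1 - exp(-tau / t1b)) * exp(-plds[s] / t1b)) /
      (6000 * acq$lambda_part)
    att <- truth$att_true[, , s]
    pld_ms <- plds[s] * 1000
    deliv <- ifelse(att <= pld_ms, 1,
                    pmax(0, 1 - (att - pld_ms) / acq$tau_label_ms))
    delivered <- full * deliv
    art <- truth$arterial_mask[, , s]
    undelivered <- sum(full) - sum(delivered)
    if (undelivered > 0 && any(art))
      delivered[art] <- delivered[art] + undelivered / sum(art)
    dm[, , s] <- delivered
  }
  dm
}

#' Simulate a whole cohort (imaging sessions plus fitness records)
#'
#' Repeatability design: two sessions per subject; the second session's true
#' GM CBF is perturbed by N(0, `between_session_sd`^2) and its ATT field is an
#' independent realization at the same calibrated dispersion. Training design:
#' baseline and follow-up sessions, with follow-up true CBF multiplied
#' per-lobe by `1 + regional_effect_pct/100` exactly, plus a long-format
#' fitness table (columns `subject_id`, `months` in {0, 3, 6}, `vo2peak`)
#' from a random-intercept-and-slope model with the configured 6-month
#' missingness.
#'
#' @param design A [cohort_design()].
#' @param acq An [asl_acquisition()].
#' @param shape Grid dimensions; its third element must match `acq$n_slices`.
#' @return List with `datasets` (list of `asl_dataset`, two per subject, with
#'   `subject_id` and `session_id` set), `fitness` (data.frame or `NULL`) and
#'   the `design`.
#' @export
simulate_cohort <- function(design, acq = asl_acquisition(),
                            shape = c(40, 40, acq$n_slices)) {
  stopifnot(inherits(design, "cohort_design"))
  datasets <- vector("list", 2L * design$n_subjects)
  lobe_factor <- if (design$design_kind == "training")
    1 + design$regional_effect_pct / 100 else NULL
  for (i in seq_len(design$n_subjects)) {
    truth1 <- make_ground_truth(shape, design, i, design$seed, acq)
    sid <- sprintf("S%02d", i)
    ds1 <- simulate_session(truth1, acq, design$within_session_noise_sd,
                            seed = subject_seed(design$seed, i, salt = 2L))
    ds1$subject_id <- sid; ds1$session_id <- 1L
    cbf2 <- truth1$cbf_gm
    if (design$between_session_sd > 0)
      cbf2 <- max(5, cbf2 + local({
        set.seed(subject_seed(design$seed, i, salt = 3L))
        stats::rnorm(1, 0, design$between_session_sd)
      }))
    # the ATT field is anatomy and stays fixed across a subject's sessions;
    # session-to-session variation enters through the global CBF perturbation
    # and thermal noise
    truth2 <- session_truth(truth1, cbf2, lobe_factor = lobe_factor)
    ds2 <- simulate_session(truth2, acq, design$within_session_noise_sd,
                            seed = subject_seed(design$seed, i, salt = 5L))
    ds2$subject_id <- sid; ds2$session_id <- 2L
    datasets[[2 * i - 1]] <- ds1
    datasets[[2 * i]] <- ds2
  }
  fitness <- NULL
  if (design$design_kind == "training")
    fitness <- simulate_fitness(design)
  list(datasets = datasets, fitness = fitness, design = design)
}

#' Simulate the three-timepoint aerobic-fitness table
#'
#' Peak oxygen uptake per subject and timepoint from
#' `vo2 = (b0 + u0_i) + b_3m I(t=3) + b_6m I(t=6) + u1_i t + e`, with random
#' intercept `u0`, random slope `u1` (per month) and residual `e`. The
#' configured number of subjects lose their 6-month row (baseline and 3-month
#' rows are never removed).
#'
#' @param design A training [cohort_design()].
#' @return Long data.frame: `subject_id`, `months` (0/3/6), `vo2peak`.
#' @export
simulate_fitness <- function(design) {
  stopifnot(inherits(design, "cohort_design"),
            design$design_kind == "training")
  fp <- design$fitness_params
  set.seed(subject_seed(design$seed, 0L, salt = 6L))
  n <- design$n_subjects
  u0 <- stats::rnorm(n, 0, fp$sd_intercept)
  u1 <- stats::rnorm(n, 0, fp$sd_slope)
  rows <- expand.grid(subject = seq_len(n), months = c(0, 3, 6))
  beta_t <- ifelse(rows$months == 3, fp$beta_3m,
                   ifelse(rows$months == 6, fp$beta_6m, 0))
  vo2 <- fp$beta0 + u0[rows$subject] + beta_t +
    u1[rows$subject] * rows$months +
    stats::rnorm(nrow(rows), 0, fp$sd_resid)
  tab <- data.frame(subject_id = sprintf("S%02d", rows$subject),
                    months = rows$months, vo2peak = vo2,
                    stringsAsFactors = FALSE)
  if (fp$n_missing_6m > 0) {
    drop <- sprintf("S%02d", sample.int(n, fp$n_missing_6m))
    tab <- tab[!(tab$months == 6 & tab$subject_id %in% drop), ]
  }
  rownames(tab) <- NULL
  tab
}

#' Simulate paired scalar metrics from programmed variance components
#'
#' Draws an n-by-k matrix `value_ij = mu + b_i + e_ij` with between-subject
#' SD `sd_between` and within-subject (session) SD `sd_within`; the true
#' single-measure absolute-agreement ICC of this model is
#' `sd_between^2 / (sd_between^2 + sd_within^2)`. Used for reliability
#' calibration studies at the metric level.
#'
#' @param n Subjects. @param k Sessions.
#' @param mu Population mean. @param sd_between,sd_within Component SDs.
#' @param seed Integer seed.
#' @return n x k numeric matrix.
#' @export
simulate_paired_metrics <- function(n, k = 2, mu = 50, sd_between = 15,
                                    sd_within = 7, seed = 1L) {
  stopifnot(n >= 2, k >= 2, sd_between >= 0, sd_within >= 0)
  set.seed(seed)
  b <- stats::rnorm(n, 0, sd_between)
  matrix(mu + rep(b, k) + stats::rnorm(n * k, 0, sd_within), nrow = n)
}

#' Simulate a lobar baseline/follow-up metric table
#'
#' Metric-level (no imaging) training-cohort generator for power and type-I
#' calibration studies of the effect statistics: per subject-lobe baseline
#' values around the population mean, with follow-up multiplied by
#' `1 + (effect_pct + noise)/100` where the noise SD is `change_sd_pct`.
#'
#' @param n Subjects.
#' @param baseline_mean,baseline_sd Population distribution of subject
#'   baseline CBF (ml/100g/min).
#' @param lobe_sd SD of lobe-to-lobe deviation around a subject's baseline.
#' @param effect_pct Named per-lobe mean percent change at follow-up.
#' @param change_sd_pct SD of per-subject-lobe percent change.
#' @param seed Integer seed.
#' @return Long data.frame: `subject_id`, `timepoint` (factor
#'   baseline/followup), `region`, `value`.
#' @export
simulate_lobe_metrics <- function(n = 8, baseline_mean = 40, baseline_sd = 13,
                                  lobe_sd = 4,
                                  effect_pct = c(frontal = 0, occipital = 0,
                                                 parietal = 18, temporal = 0),
                                  change_sd_pct = 8, seed = 1L) {
  lobes <- c("frontal", "occipital", "parietal", "temporal")
  stopifnot(setequal(names(effect_pct), lobes))
  effect_pct <- effect_pct[lobes]
  set.seed(seed)
  base_subj <- pmax(5, stats::rnorm(n, baseline_mean, baseline_sd))
  rows <- expand.grid(subject = seq_len(n), region = lobes,
                      stringsAsFactors = FALSE)
  bl <- pmax(1, base_subj[rows$subject] + stats::rnorm(nrow(rows), 0, lobe_sd))
  chg <- effect_pct[rows$region] + stats::rnorm(nrow(rows), 0, change_sd_pct)
  fu <- bl * (1 + chg / 100)
  out <- rbind(
    data.frame(subject_id = sprintf("S%02d", rows$subject),
               timepoint = "baseline", region = rows$region, value = bl,
               stringsAsFactors = FALSE),
    data.frame(subject_id = sprintf("S%02d", rows$subject),
               timepoint = "followup", region = rows$region, value = fu,
               stringsAsFactors = FALSE))
  out$timepoint <- factor(out$timepoint, levels = c("baseline", "followup"))
  rownames(out) <- NULL
  out
}
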