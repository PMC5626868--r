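#' Control-minus-tag difference series
#'
#' @param ds An `asl_dataset`.
#' @param sign_flip If `TRUE`, compute tag minus control (some vendor
#'   dialects store the pair in the opposite order).
#' @return 4D array, one difference volume per control/tag pair, order
#'   preserved.
#' @export
delta_series <- function(ds, sign_flip = FALSE) {
  stopifnot(inherits(ds, "asl_dataset"))
  if (!identical(dim(ds$control), dim(ds$tag)))
    stop("control and tag series have mismatched shapes")
  d <- ds$control - ds$tag
  if (sign_flip) d <- -d
  d
}

#' Select control/tag pairs maximizing gray-matter SNR
#'
#' Greedy SNR optimization of the averaged difference image: volumes are
#' ranked by agreement with the voxelwise median difference volume over the
#' GM mask, the retained set grows in that order, and the prefix maximizing
#' the GM SNR of the running mean — mean over GM divided by the standard
#' error across GM voxels — is returned. At least
#' `max(2, ceiling(min_frac * n))` volumes are always retained; exact SNR
#' ties resolve toward the larger set, so identical volumes are all kept.
#'
#' Agreement is measured by Lin's concordance correlation coefficient rather
#' than Pearson correlation: volume-level gain spikes (the corruption mode of
#' motion-degraded ASL volumes) rescale a volume without changing its Pearson
#' correlation with the median, and only a scale- and shift-sensitive
#' agreement index can rank them last.
#'
#' @param diff 4D difference series.
#' @param gm_mask 3D logical gray-matter mask.
#' @param min_frac Minimum fraction of volumes to retain.
#' @return Sorted integer indices of retained volumes.
#' @export
select_volumes <- function(diff, gm_mask, min_frac = 0.2) {
  stopifnot(length(dim(diff)) == 4)
  n <- dim(diff)[4]
  if (n < 2) stop("need at least 2 volumes")
  if (!any(gm_mask)) stop("gray-matter mask is empty")
  V <- matrix(diff, ncol = n)[as.vector(gm_mask), , drop = FALSE]
  med <- apply(V, 1, stats::median)
  vm <- mean(med); vv <- stats::var(med)
  ccc <- vapply(seq_len(n), function(i) {
    x <- V[, i]
    2 * stats::cov(x, med) / (stats::var(x) + vv + (mean(x) - vm)^2)
  }, numeric(1))
  ord <- order(ccc, decreasing = TRUE)
  ngm <- nrow(V)
  run <- rep(0, ngm)
  snr <- numeric(n)
  for (j in seq_len(n)) {
    run <- run + V[, ord[j]]
    m <- run / j
    s <- stats::sd(m)
    snr[j] <- if (s == 0) Inf else mean(m) / (s / sqrt(ngm))
  }
  jmin <- max(2L, ceiling(min_frac * n))
  snr[seq_len(jmin - 1L)] <- -Inf
  best <- max(snr)
  jstar <- if (is.infinite(best) && best > 0) max(which(snr == Inf))
           else max(which(snr >= best - 1e-9 * abs(best)))
  sort(ord[seq_len(jstar)])
}

#' 3D Gaussian smoothing
#'
#' Separable Gaussian convolution with per-axis
#' `sigma = fwhm_mm / (2.3548 * voxel_mm)` voxels and symmetric-reflect
#' boundary handling (which conserves the image sum). `fwhm_mm = 0` returns
#' the input unchanged.
#'
#' @param vol 3D array.
#' @param fwhm_mm Kernel full width at half maximum, mm.
#' @param voxel_mm Length-3 voxel edge lengths, mm.
#' @return Smoothed 3D array.
#' @export
smooth_map <- function(vol, fwhm_mm, voxel_mm) {
  stopifnot(length(dim(vol)) == 3, length(voxel_mm) == 3, all(voxel_mm > 0))
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(vol)
  gaussian_smooth3d(vol, sigma_vox = fwhm_mm / (2.3548 * voxel_mm))
}

# Separable 3D Gaussian convolution; sigma_vox per axis in voxel units.
# Implemented as banded convolution matrices with symmetric reflection.
gaussian_smooth3d <- function(vol, sigma_vox) {
  d <- dim(vol)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    n <- d[ax]
    rad <- max(1L, ceiling(3 * s))
    w <- stats::dnorm(-rad:rad, sd = s)
    w <- w / sum(w)
    K <- matrix(0, n, n)
    for (off in -rad:rad) {
      idx <- seq_len(n) + off
      # symmetric reflection: ..., 2, 1 | 1, 2, ..., n | n, n-1, ...
      idx <- ifelse(idx < 1, 1 - idx, idx)
      idx <- ifelse(idx > n, 2 * n + 1 - idx, idx)
      K[cbind(seq_len(n), idx)] <- K[cbind(seq_len(n), idx)] + w[off + rad + 1]
    }
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    v <- aperm(vol, perm)
    dp <- dim(v)
    v <- K %*% matrix(v, nrow = dp[1])
    dim(v) <- dp
    vol <- aperm(v, order(perm))
  }
  vol
}

#' Quantify CBF from a mean difference image
#'
#' Single-compartment kinetic model with slice-wise PLD: for a voxel in
#' slice `s` (1-based),
#' \deqn{CBF = \frac{6000\,\lambda\,\Delta M\, e^{PLD_s/T_{1b}}}
#'   {2\,\alpha\, T_{1b}\, M_0 (1 - e^{-\tau/T_{1b}})}}
#' in ml/100g/min, with `PLD_s = pld0 + (s-1) * slice_dt` and times in
#' seconds. Voxels whose M0 falls below 10 percent of the robust (90th
#' percentile) brain M0 are set to `NA`: they are unreliable divisions at
#' mask edges and are excluded from all downstream metrics.
#'
#' @param mean_diff 3D mean control-minus-tag image.
#' @param m0 3D equilibrium-magnetization image, positive over the head.
#' @param acq An [asl_acquisition()].
#' @return 3D CBF map (ml/100g/min), `NA` outside reliable M0 support.
#' @export
quantify_cbf <- function(mean_diff, m0, acq) {
  stopifnot(inherits(acq, "asl_acq"),
            identical(dim(mean_diff), dim(m0)),
            length(dim(m0)) == 3)
  if (dim(m0)[3] != acq$n_slices)
    stop("third dimension must equal acq$n_slices")
  t1b <- acq$t1_blood_ms / 1000
  tau <- acq$tau_label_ms / 1000
  plds <- slice_plds(acq) / 1000
  floor_m0 <- 0.1 * stats::quantile(m0[m0 > 0], 0.9, names = FALSE)
  cbf <- array(NA_real_, dim(m0))
  for (s in seq_len(acq$n_slices)) {
    ok <- m0[, , s] >= floor_m0
    num <- 6000 * acq$lambda_part * mean_diff[, , s] * exp(plds[s] / t1b)
    den <- 2 * acq$alpha_eff * t1b * m0[, , s] * (1 - exp(-tau / t1b))
    sl <- ifelse(ok, num / den, NA_real_)
    cbf[, , s] <- sl
  }
  cbf
}

#' Gray-matter analysis mask
#'
#' Thresholds the GM partial-volume map and removes the ischemic lesion:
#' `mask = (pv_gm >= threshold) & !lesion_mask`. Lesion voxels are excluded
#' regardless of their GM fraction.
#'
#' @param pv_gm 3D GM partial-volume fractions in [0, 1].
#' @param lesion_mask 3D logical lesion mask (or `NULL` for none).
#' @param threshold GM partial-volume threshold in [0, 1].
#' @return 3D logical mask.
#' @export
make_gm_mask <- function(pv_gm, lesion_mask = NULL, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  stopifnot(all(pv_gm >= 0 & pv_gm <= 1))
  mask <- pv_gm >= threshold
  if (threshold == 0) mask <- pv_gm > 0
  if (!is.null(lesion_mask)) mask <- mask & !lesion_mask
  mask
}

#' Regional CBF and spatial-CoV metrics
#'
#' Computes mean CBF and spatial coefficient of variation
#' (`100 * sample SD / mean`) over global gray matter and the four cortical
#' lobes, and mean CBF over the lesion (assessed separately, no sCoV). A
#' region entirely outside the acquisition coverage is omitted — subtentorial
#' lesions can fall outside the ASL field of view. A region whose mean CBF is
#' not positive gets an undefined (NA) sCoV with a warning.
#'
#' @param cbf_map 3D CBF map (NA allowed).
#' @param gm_mask 3D logical mask actually analyzed (lesion already removed).
#' @param lobe_atlas 3D integer lobe labels (0 none, 1 frontal, 2 occipital,
#'   3 parietal, 4 temporal).
#' @param lesion_mask 3D logical lesion mask, or `NULL`.
#' @param coverage 3D logical acquisition coverage, or `NULL` for full.
#' @param subject_id,session_id Identifiers copied into every row.
#' @return Data frame with columns `subject_id`, `session_id`, `region`
#'   (global_gm, frontal, occipital, parietal, temporal, lesion),
#'   `mean_cbf`, `scov_pct` (NA for lesion), `n_voxels`.
#' @export
roi_metrics <- function(cbf_map, gm_mask, lobe_atlas, lesion_mask = NULL,
                        coverage = NULL, subject_id = NA_character_,
                        session_id = NA_integer_) {
  stopifnot(identical(dim(cbf_map), dim(gm_mask)))
  if (!all(unique(as.integer(lobe_atlas)) %in% 0:4))
    stop("lobe_atlas labels must be in 0..4")
  if (is.null(coverage)) coverage <- array(TRUE, dim(cbf_map))
  usable <- coverage & !is.na(cbf_map)
  lobes <- c(frontal = 1L, occipital = 2L, parietal = 3L, temporal = 4L)
  regions <- list(global_gm = gm_mask)
  for (nm in names(lobes)) regions[[nm]] <- gm_mask & lobe_atlas == lobes[nm]
  rows <- list()
  for (nm in names(regions)) {
    idx <- regions[[nm]] & usable
    nvox <- sum(idx)
    if (nvox == 0) next
    vals <- cbf_map[idx]
    m <- mean(vals)
    scov <- if (m > 0 && nvox > 1) 100 * stats::sd(vals) / m else NA_real_
    if (m <= 0)
      warning("region '", nm, "' has non-positive mean CBF; ",
              "sCoV undefined", call. = FALSE)
    rows[[length(rows) + 1]] <-
      data.frame(subject_id = subject_id, session_id = session_id,
                 region = nm, mean_cbf = m, scov_pct = scov,
                 n_voxels = nvox, stringsAsFactors = FALSE)
  }
  if (!is.null(lesion_mask)) {
    idx <- lesion_mask & usable
    if (sum(idx) > 0) {
      rows[[length(rows) + 1]] <-
        data.frame(subject_id = subject_id, session_id = session_id,
                   region = "lesion", mean_cbf = mean(cbf_map[idx]),
                   scov_pct = NA_real_, n_voxels = sum(idx),
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Quantification pipeline configuration
#'
#' @param fwhm_mm Smoothing kernel FWHM, mm; `NULL` uses the acquisition's.
#' @param gm_threshold GM partial-volume threshold.
#' @param select Run SNR-optimizing volume selection.
#' @param min_retain_frac Minimum fraction of volumes the selection keeps.
#' @param smooth_before_quantify If `TRUE` (default) the mean difference
#'   image is smoothed before the kinetic inversion; if `FALSE` the CBF map
#'   is smoothed instead.
#' @param sign_flip Flip the control/tag sign convention.
#' @return A config list.
#' @export
quantify_config <- function(fwhm_mm = NULL, gm_threshold = 0.5,
                            select = TRUE, min_retain_frac = 0.2,
                            smooth_before_quantify = TRUE,
                            sign_flip = FALSE) {
  list(fwhm_mm = fwhm_mm, gm_threshold = gm_threshold, select = select,
       min_retain_frac = min_retain_frac,
       smooth_before_quantify = smooth_before_quantify,
       sign_flip = sign_flip)
}

#' Run the full single-session quantification pipeline
#'
#' Ordered composition: difference series, SNR-optimizing volume selection,
#' averaging of retained pairs, spatial smoothing, slice-wise kinetic
#' inversion, GM masking (lesion excluded), regional metrics. Deterministic
#' given its inputs.
#'
#' @param ds An `asl_dataset` (its `truth` supplies the masks and atlas).
#' @param config A [quantify_config()].
#' @param coverage Optional 3D logical acquisition-coverage mask.
#' @return List with `result` (class `perfusion_result`: `cbf_map`,
#'   `retained_pairs`, `gm_mask`, `n_excluded`) and `metrics`
#'   (the [roi_metrics()] data frame).
#' @export
run_session <- function(ds, config = quantify_config(), coverage = NULL) {
  stopifnot(inherits(ds, "asl_dataset"))
  if (is.null(ds$truth))
    stop("run_session needs tissue maps; dataset has no truth attached")
  fwhm <- if (is.null(config$fwhm_mm)) ds$acq$fwhm_mm else config$fwhm_mm
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  diff <- stage("delta", delta_series(ds, config$sign_flip))
  gm_sel <- stage("mask", make_gm_mask(ds$truth$pv_gm, ds$truth$lesion_mask,
                                       config$gm_threshold))
  n <- dim(diff)[4]
  retained <- if (isTRUE(config$select) && n >= 2)
    stage("select", select_volumes(diff, gm_sel, config$min_retain_frac))
  else seq_len(n)
  mean_diff <- stage("average",
                     apply(diff[, , , retained, drop = FALSE], 1:3, mean))
  if (isTRUE(config$smooth_before_quantify)) {
    mean_diff <- stage("smooth",
                       smooth_map(mean_diff, fwhm, ds$acq$voxel_mm))
    cbf <- stage("quantify", quantify_cbf(mean_diff, ds$m0, ds$acq))
  } else {
    cbf <- stage("quantify", quantify_cbf(mean_diff, ds$m0, ds$acq))
    smoothed <- stage("smooth", {
      tmp <- cbf; tmp[is.na(tmp)] <- 0
      sm <- smooth_map(tmp, fwhm, ds$acq$voxel_mm)
      sm[is.na(cbf)] <- NA_real_
      sm
    })
    cbf <- smoothed
  }
  metrics <- stage("metrics",
                   roi_metrics(cbf, gm_sel, ds$truth$lobe_atlas,
                               ds$truth$lesion_mask, coverage,
                               ds$subject_id, ds$session_id))
  result <- structure(list(cbf_map = cbf, retained_pairs = retained,
                           gm_mask = gm_sel,
                           n_excluded = n - length(retained)),
                      class = "perfusion_result")
  list(result = result, metrics = metrics)
}
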