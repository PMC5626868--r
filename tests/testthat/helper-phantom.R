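# Small-scale phantom builders shared across test files.

small_acq <- function(n_slices = 8, n_pairs = 8, voxel_mm = c(8, 8, 5),
                      ...) {
  asl_acquisition(n_slices = n_slices, n_pairs = n_pairs,
                  voxel_mm = voxel_mm, ...)
}

small_truth <- function(shape = c(20, 20, 8), acq = small_acq(),
                        scov_target_pct = 25, mean_gm_cbf = 51,
                        sd_gm_cbf = 0, seed = 11, subject = 1L,
                        lesion_radius_vox = NULL, ...) {
  des <- cohort_design("repeatability", mean_gm_cbf = mean_gm_cbf,
                       sd_gm_cbf = sd_gm_cbf,
                       scov_target_pct = scov_target_pct,
                       lesion_radius_vox = lesion_radius_vox,
                       seed = seed, ...)
  make_ground_truth(shape, des, subject, acq = acq)
}

# 1x1x1 "voxel phantom" for closed-form kinetic checks.
voxel_truth <- function(cbf = 80.3, att = 500) {
  one <- function(v) array(v, c(1, 1, 1))
  structure(list(
    cbf_true = one(cbf), att_true = one(att),
    pv_gm = one(1), pv_wm = one(0), pv_csf = one(0),
    lobe_atlas = array(1L, c(1, 1, 1)),
    arterial_mask = one(FALSE) > 0, lesion_mask = one(FALSE) > 0,
    brain_mask = one(TRUE) > 0,
    cbf_gm = cbf, scov_target_pct = 0, att_sd_ms = 0, att_base_ms = att
  ), class = "asl_truth")
}

voxel_acq <- function(pld0_ms = 1600) {
  asl_acquisition(tau_label_ms = 1650, pld0_ms = pld0_ms, slice_dt_ms = 0,
                  n_slices = 1, voxel_mm = c(3, 3, 5), n_pairs = 2,
                  alpha_eff = 0.85, t1_blood_ms = 1650, lambda_part = 0.9)
}
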