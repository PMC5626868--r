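test_that("acquisition parameters validate and expose the slice PLD schedule", {
  acq <- asl_acquisition()
  expect_equal(acq$tau_label_ms, 1650)
  plds <- slice_plds(acq)
  expect_length(plds, 18)
  expect_equal(plds[1], 1600)
  expect_equal(diff(plds), rep(acq$slice_dt_ms, 17))
  expect_true(all(diff(plds) >= 0))
  expect_error(asl_acquisition(alpha_eff = 1.2), "alpha_eff")
  expect_error(asl_acquisition(tau_label_ms = 0), "tau_label_ms")
  expect_error(asl_acquisition(n_pairs = 0), "n_pairs")
})

test_that("ground truth is deterministic, physical, and sized-checked", {
  acq <- small_acq()
  t1 <- small_truth(seed = 3, subject = 2)
  t2 <- small_truth(seed = 3, subject = 2)
  expect_identical(t1, t2)
  t3 <- small_truth(seed = 3, subject = 3)
  expect_false(identical(t1$cbf_true, t3$cbf_true))

  expect_true(all(t1$pv_gm + t1$pv_wm + t1$pv_csf <= 1 + 1e-12))
  expect_true(all(t1$cbf_true >= 0))
  expect_true(all(t1$att_true > 0))
  expect_true(all(sort(unique(as.integer(t1$lobe_atlas))) %in% 0:4))
  for (k in 1:4) expect_gt(sum(t1$lobe_atlas == k), 0)

  expect_error(make_ground_truth(c(8, 8, 4), cohort_design("repeatability")),
               "16 x 16 x 8")
})

test_that("subject-level true GM CBF follows the programmed distribution", {
  des0 <- cohort_design("repeatability", sd_gm_cbf = 0, scov_target_pct = 0)
  tr <- make_ground_truth(c(16, 16, 8), des0, 1,
                          acq = small_acq(n_slices = 8))
  expect_equal(tr$cbf_gm, 51)
  gm <- tr$lobe_atlas > 0
  expect_equal(mean(tr$cbf_true[gm & !tr$lesion_mask]), 51)

  des <- cohort_design("repeatability", scov_target_pct = 0, seed = 5)
  acq8 <- small_acq(n_slices = 8)
  draws <- vapply(1:200, function(i)
    make_ground_truth(c(16, 16, 8), des, i, acq = acq8)$cbf_gm, numeric(1))
  expect_lt(abs(mean(draws) - 51), 3)
  expect_lt(abs(sd(draws) - 15), 5)
})

test_that("lesion halves local true CBF and scales with the brain", {
  tr <- small_truth(seed = 7)
  expect_gt(sum(tr$lesion_mask), 0)
  les_gm <- tr$lesion_mask & tr$lobe_atlas > 0
  if (any(les_gm))
    expect_equal(unique(round(tr$cbf_true[les_gm] / tr$cbf_gm, 10)), 0.5)
  tr0 <- small_truth(seed = 7, lesion_radius_vox = 0)
  expect_equal(sum(tr0$lesion_mask), 0)
})

test_that("the forward kinetic model matches its closed form", {
  tr <- voxel_truth(cbf = 80.3, att = 500)
  acq <- voxel_acq()
  ds <- simulate_session(tr, acq, noise_sd = 0, seed = 1)
  dm <- (ds$control - ds$tag)[1, 1, 1, 1]
  expect_equal(dm, 10, tolerance = 1e-3)
  # analytic value of the forward equation at these constants
  t1b <- 1.65
  expect_equal(dm,
               2 * 0.85 * 1000 * 80.3 * t1b * (1 - exp(-1)) *
                 exp(-1.6 / t1b) / (6000 * 0.9),
               tolerance = 1e-12)
})

test_that("noiseless sessions reproduce the difference signal exactly", {
  acq <- small_acq(n_pairs = 4)
  tr <- small_truth(scov_target_pct = 0)
  ds <- simulate_session(tr, acq, noise_sd = 0, seed = 2)
  d <- delta_series(ds)
  md <- apply(d, 1:3, mean)
  expect_identical(d[, , , 1], d[, , , 4])
  # ATT <= PLD everywhere (dispersion 0, base 1200 < 1600): pure kinetics
  expect_true(all(abs(md - d[, , , 1]) < 1e-12))

  tr0 <- tr
  tr0$cbf_true[] <- 0
  ds0 <- simulate_session(tr0, acq, noise_sd = 0.5, seed = 3)
  d0 <- delta_series(ds0)
  expect_lt(abs(mean(d0)), 0.05)
  expect_error(simulate_session(tr, acq, noise_sd = -1), "noise_sd")
})

test_that("label mass is conserved per slice under ATT re-deposition", {
  acq <- small_acq(n_pairs = 2)
  tr_low <- small_truth(scov_target_pct = 0, seed = 9)
  tr_high <- small_truth(scov_target_pct = 40, seed = 9)
  expect_identical(tr_low$cbf_true, tr_high$cbf_true)
  ds_low <- simulate_session(tr_low, acq, 0, 1)
  ds_high <- simulate_session(tr_high, acq, 0, 1)
  dm_low <- (ds_low$control - ds_low$tag)[, , , 1]
  dm_high <- (ds_high$control - ds_high$tag)[, , , 1]
  for (s in seq_len(dim(dm_low)[3]))
    expect_equal(sum(dm_high[, , s]), sum(dm_low[, , s]), tolerance = 1e-9)
})

test_that("ATT dispersion calibration is monotone and hits its target", {
  plds <- slice_plds(small_acq())
  sds <- vapply(c(10, 25, 40), att_sd_for_scov, numeric(1),
                plds_ms = plds)
  expect_true(all(diff(sds) > 0))
  for (i in seq_along(sds)) {
    got <- strokeflow:::delivery_moments(sds[i], plds)$cov_pct
    expect_equal(got, c(10, 25, 40)[i], tolerance = 0.05)
  }
  expect_equal(att_sd_for_scov(0, plds), 0)
})

test_that("repeatability cohorts degenerate correctly and stay deterministic", {
  acq <- small_acq(n_pairs = 2)
  des <- cohort_design("repeatability", n_subjects = 2,
                       within_session_noise_sd = 0, between_session_sd = 0,
                       scov_target_pct = 20, seed = 4)
  coh <- simulate_cohort(des, acq, shape = c(16, 16, 8))
  expect_length(coh$datasets, 4)
  expect_identical(coh$datasets[[1]]$control, coh$datasets[[2]]$control)
  coh2 <- simulate_cohort(des, acq, shape = c(16, 16, 8))
  expect_identical(coh, coh2)
  expect_null(coh$fitness)
})

test_that("training cohorts apply the programmed lobe effect exactly", {
  acq <- small_acq(n_pairs = 2)
  des <- cohort_design("training", n_subjects = 2,
                       within_session_noise_sd = 0,
                       regional_effect_pct = c(frontal = 0, occipital = 0,
                                               parietal = 18, temporal = 0),
                       seed = 6)
  coh <- simulate_cohort(des, acq, shape = c(16, 16, 8))
  for (i in 1:2) {
    bl <- coh$datasets[[2 * i - 1]]$truth
    fu <- coh$datasets[[2 * i]]$truth
    par <- bl$lobe_atlas == 3 & !bl$lesion_mask
    expect_equal(fu$cbf_true[par] / bl$cbf_true[par],
                 rep(1.18, sum(par)), tolerance = 1e-12)
    fro <- bl$lobe_atlas == 1 & !bl$lesion_mask
    expect_equal(fu$cbf_true[fro], bl$cbf_true[fro], tolerance = 1e-12)
  }
})

test_that("the fitness table has the programmed shape and missingness", {
  des <- cohort_design("training", seed = 2)
  fit <- simulate_fitness(des)
  expect_equal(nrow(fit), 8 + 8 + 4)
  expect_equal(sum(fit$months == 0), 8)
  expect_equal(sum(fit$months == 3), 8)
  expect_equal(sum(fit$months == 6), 4)

  des2 <- cohort_design("training",
                        fitness_params = list(n_missing_6m = 0L), seed = 2)
  expect_equal(nrow(simulate_fitness(des2)), 24)
  expect_error(cohort_design("training",
                             regional_effect_pct = c(frontal = 1)),
               "4 lobes")
  expect_error(cohort_design("nonsense"), "arg")
})

test_that("metric-level simulators honour their variance components", {
  X <- simulate_paired_metrics(2000, mu = 50, sd_between = 10, sd_within = 0,
                               seed = 8)
  expect_equal(X[, 1], X[, 2])
  expect_lt(abs(sd(X[, 1]) - 10), 1)
  tab <- simulate_lobe_metrics(n = 6, effect_pct = c(frontal = 0,
                                                     occipital = 0,
                                                     parietal = 10,
                                                     temporal = 0),
                               change_sd_pct = 0, lobe_sd = 0, seed = 1)
  w <- tab[tab$region == "parietal", ]
  r <- w$value[w$timepoint == "followup"] / w$value[w$timepoint == "baseline"]
  expect_equal(r, rep(1.10, 6), tolerance = 1e-12)
})
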