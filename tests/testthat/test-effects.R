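test_that("paired t matches hand computation and its symmetries", {
  v0 <- c(10, 20, 30, 40)
  same <- paired_t(v0, v0)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  v1 <- v0 + c(1, 2, 3, 4)
  r <- paired_t(v0, v1)
  expect_equal(r$t, 3.872983, tolerance = 1e-6)
  expect_equal(r$df, 3)
  expect_equal(r$p, 0.0304663, tolerance = 1e-6)

  flipped <- paired_t(v1, v0)
  expect_equal(flipped$t, -r$t, tolerance = 1e-12)
  expect_equal(flipped$p, r$p, tolerance = 1e-12)

  expect_warning(rz <- paired_t(c(1, 2, 3), c(2, 3, 4)), "zero variance")
  expect_equal(rz$p, 0)
})

test_that("RM-ANOVA matches the brute-force sums-of-squares oracle", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(5:8, 1)
    tab <- simulate_lobe_metrics(n = n, effect_pct = c(frontal = 5,
                                                       occipital = 0,
                                                       parietal = 12,
                                                       temporal = -3),
                                 change_sd_pct = 10, seed = 100 + rep)
    got <- rm_anova_interaction(tab)
    want <- brute_rm_anova(tab)
    expect_lt(abs(got$interaction$F - want$F_inter), 1e-10)
    expect_lt(abs(got$time$F - want$F_time), 1e-10)
    expect_lt(abs(got$region$F - want$F_region), 1e-10)
    expect_equal(got$interaction$df1, 3)
    expect_equal(got$interaction$df2, 3 * (n - 1))
  }
})

test_that("RM-ANOVA interaction vanishes for a region-uniform time effect", {
  tab <- simulate_lobe_metrics(n = 8, effect_pct = c(frontal = 0,
                                                     occipital = 0,
                                                     parietal = 0,
                                                     temporal = 0),
                               change_sd_pct = 0, seed = 3)
  # identical +4 ml/100g/min shift in every region at follow-up: the
  # time-by-region sum of squares vanishes (to rounding) while the time
  # effect is carried entirely by its main-effect stratum
  tab$value[tab$timepoint == "followup"] <-
    tab$value[tab$timepoint == "baseline"] + 4
  got <- rm_anova_interaction(tab)
  expect_equal(got$interaction$df2, 21)
  expect_lt(got$interaction$ss, 1e-10 * got$time$ss)
  expect_gt(got$time$F, 1e6)

  tab2 <- tab[!(tab$subject_id == "S01" & tab$timepoint == "followup" &
                  tab$region == "parietal"), ]
  expect_error(rm_anova_interaction(tab2), "incomplete")
})

test_that("the squared paired t equals the time main-effect F", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(5:9, 1)
    v0 <- rnorm(n, 40, 10)
    v1 <- v0 + rnorm(n, 2, 4)
    tab <- data.frame(subject_id = rep(sprintf("S%02d", 1:n), 2),
                      timepoint = rep(c("baseline", "followup"), each = n),
                      region = "global", value = c(v0, v1))
    f <- rm_anova_interaction(tab)$time$F
    t2 <- paired_t(v0, v1)$t^2
    expect_lt(abs(f - t2), 1e-8)
  }
})

test_that("Bonferroni post hocs multiply, cap, and never shrink p", {
  set.seed(5)
  tab <- simulate_lobe_metrics(n = 8, seed = 17)
  ph <- posthoc_lobes(tab)
  expect_equal(nrow(ph), 4)
  expect_equal(ph$p_bonferroni, pmin(1, 4 * ph$p), tolerance = 1e-12)
  expect_true(all(ph$p_bonferroni >= ph$p))
  expect_true(all(ph$p_bonferroni <= 1))
})

test_that("paired Hedges' g matches its formula and flips with order", {
  v1 <- c(1, 1, 1, 3, 2, 0, 2, 2)
  v0 <- rep(0, 8)
  r <- hedges_g_paired(v0, v1)
  expect_equal(r$g, (1 - 3 / 27) * 1.5 / sd(v1), tolerance = 1e-12)
  expect_equal(r$g, 1.440165, tolerance = 1e-5)
  expect_equal(hedges_g_paired(v1, v0)$g, -r$g, tolerance = 1e-12)

  null <- hedges_g_paired(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(null$g, 0)
  expect_equal(null$lower, -null$upper, tolerance = 1e-12)

  avg <- hedges_g_paired(v0, v1, standardizer = "average")
  expect_false(isTRUE(all.equal(avg$g, r$g)))
  expect_warning(hedges_g_paired(c(1, 1, 1), c(2, 2, 2)), "standardizer")
})

test_that("the fitness mixed model collapses to timepoint means when balanced", {
  des <- cohort_design("training",
                       fitness_params = list(sd_intercept = 0, sd_slope = 0,
                                             sd_resid = 1.0,
                                             n_missing_6m = 0L),
                       n_subjects = 10, seed = 31)
  fit <- simulate_fitness(des)
  r <- fit_fitness_lmm(fit)
  means <- tapply(fit$vo2peak, fit$months, mean)
  expect_equal(r$fixed$estimate[r$fixed$term == "3-month"],
               unname(means["3"] - means["0"]), tolerance = 1e-6)
  expect_equal(r$fixed$estimate[r$fixed$term == "6-month"],
               unname(means["6"] - means["0"]), tolerance = 1e-6)
})

test_that("the fitness mixed model uses all rows despite missing follow-ups", {
  des <- cohort_design("training", seed = 13)
  fit <- simulate_fitness(des)
  r <- fit_fitness_lmm(fit)
  expect_equal(nrow(r$fixed), 3)
  expect_true(all(is.finite(r$fixed$estimate)))
  expect_true(all(is.finite(r$fixed$p)))
  # removing more 6-month rows still returns all three fixed effects
  fit2 <- fit[!(fit$months == 6 & fit$subject_id %in% c("S01", "S02")), ]
  r2 <- fit_fitness_lmm(fit2)
  expect_equal(nrow(r2$fixed), 3)
  expect_error(fit_fitness_lmm(fit[fit$months == 0, ]), "timepoints")
})

test_that("the fitness generator's fixed effects are recovered across cohorts", {
  ests <- t(vapply(1:100, function(r) {
    des <- cohort_design("training", seed = 1000 + r)
    fx <- fit_fitness_lmm(simulate_fitness(des))$fixed
    c(fx$estimate[fx$term == "3-month"], fx$estimate[fx$term == "6-month"])
  }, numeric(2)))
  se <- apply(ests, 2, sd) / sqrt(nrow(ests))
  expect_lt(abs(mean(ests[, 1]) - 4.9), 3 * se[1])
  expect_lt(abs(mean(ests[, 2]) - 3.5), 3 * se[2])
})

test_that("sample size search is monotone in the effect size", {
  f <- c(0.1, 0.15, 0.2, 0.27, 0.4, 0.8)
  ns <- vapply(f, function(x) sample_size_rm_anova(x)$n, numeric(1))
  expect_true(all(diff(ns) <= 0))
  expect_error(sample_size_rm_anova(0), "effect_f")
  expect_error(sample_size_rm_anova(0.3, alpha = 1.2), "alpha")
  expect_error(sample_size_rm_anova(0.3, rho = 1), "rho")
})

test_that("percent change follows its definition", {
  expect_equal(pct_change(40, 46), 15)
  expect_equal(pct_change(50, 50), 0)
  expect_error(pct_change(0, 10), "baseline")
})

test_that("the effect report assembles every endpoint", {
  des <- cohort_design("training", seed = 2)
  acq <- small_acq(n_pairs = 4)
  coh <- simulate_cohort(des, acq, shape = c(20, 20, 8))
  metrics <- do.call(rbind, lapply(coh$datasets, function(ds)
    run_session(ds, quantify_config())$metrics))
  rep_ <- effect_report(metrics, coh$fitness)
  expect_s3_class(rep_, "effect_report")
  expect_equal(nrow(rep_$posthoc), 4)
  expect_named(rep_$pct_change,
               c("global_gm", "frontal", "occipital", "parietal", "temporal"))
  expect_true(rep_$sample_size$global_cbf >= 2)
  expect_equal(rep_$interaction_cbf$interaction$df2, 3 * (des$n_subjects - 1))
  expect_output(print(rep_), "post hocs")
})
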