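quantify_all_sessions <- function(datasets, config) {
  metrics <- lapply(datasets, function(ds) run_session(ds, config)$metrics)
  out <- do.call(rbind, metrics)
  rownames(out) <- NULL
  out
}

# Echo every constant that affects a reported number, so a run can be
# reproduced from its output directory alone.
write_config_echo <- function(out_dir, design, acq, config, shape) {
  echo <- list(design = unclass(design), acquisition = unclass(acq),
               quantify = config, grid_shape = as.integer(shape))
  yaml::write_yaml(echo, file.path(out_dir, "config_echo.yaml"))
}

#' Run the full repeatability study
#'
#' One call from phantom to reliability table: simulates the two-session
#' repeatability cohort, quantifies every session, and computes the
#' region-by-metric reliability report (ICC, within-subject CoV,
#' Bland-Altman summaries). Deterministic given the design seed.
#'
#' @param design A repeatability [cohort_design()].
#' @param acq An [asl_acquisition()].
#' @param shape Phantom grid dimensions.
#' @param config A [quantify_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `metrics.csv`, `reliability.csv` and `config_echo.yaml`.
#' @return List: `metrics` (per subject x session x region) and `report`
#'   (the [reliability_report()] data frame).
#' @export
run_repeatability_study <- function(design = cohort_design("repeatability"),
                                    acq = asl_acquisition(),
                                    shape = c(40, 40, acq$n_slices),
                                    config = quantify_config(),
                                    out_dir = NULL) {
  stopifnot(design$design_kind == "repeatability")
  cohort <- simulate_cohort(design, acq, shape)
  metrics <- quantify_all_sessions(cohort$datasets, config)
  report <- reliability_report(metrics)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_metrics_csv(metrics, file.path(out_dir, "metrics.csv"))
    utils::write.csv(report, file.path(out_dir, "reliability.csv"),
                     row.names = FALSE)
    write_config_echo(out_dir, design, acq, config, shape)
  }
  list(metrics = metrics, report = report)
}

#' Run the full training study
#'
#' Simulates the baseline/6-month training cohort (imaging plus fitness),
#' quantifies every session, computes the effect report, and optionally
#' writes per-subject baseline, follow-up and relative-change CBF maps as
#' NIfTI (`100 * (followup - baseline) / baseline`, restricted to voxels
#' with baseline CBF above 1 ml/100g/min).
#'
#' @inheritParams run_repeatability_study
#' @param design A training [cohort_design()].
#' @return List: `metrics`, `report` (an [effect_report()]), `fitness`.
#' @export
run_training_study <- function(design = cohort_design("training"),
                               acq = asl_acquisition(),
                               shape = c(40, 40, acq$n_slices),
                               config = quantify_config(),
                               out_dir = NULL) {
  stopifnot(design$design_kind == "training")
  cohort <- simulate_cohort(design, acq, shape)
  runs <- lapply(cohort$datasets, function(ds) run_session(ds, config))
  metrics <- do.call(rbind, lapply(runs, `[[`, "metrics"))
  rownames(metrics) <- NULL
  report <- effect_report(metrics, cohort$fitness)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_metrics_csv(metrics, file.path(out_dir, "metrics.csv"))
    write_fitness_csv(cohort$fitness, file.path(out_dir, "fitness.csv"))
    utils::write.csv(report$posthoc, file.path(out_dir, "posthoc.csv"),
                     row.names = FALSE)
    vx <- acq$voxel_mm
    for (i in seq_len(design$n_subjects)) {
      bl <- runs[[2 * i - 1]]$result$cbf_map
      fu <- runs[[2 * i]]$result$cbf_map
      sid <- cohort$datasets[[2 * i - 1]]$subject_id
      rel <- array(NA_real_, dim(bl))
      ok <- !is.na(bl) & !is.na(fu) & bl > 1
      rel[ok] <- 100 * (fu[ok] - bl[ok]) / bl[ok]
      RNifti::writeNifti(nifti_with_voxels(bl, vx),
                         file.path(out_dir, paste0(sid, "_cbf_bl.nii.gz")))
      RNifti::writeNifti(nifti_with_voxels(fu, vx),
                         file.path(out_dir, paste0(sid, "_cbf_6m.nii.gz")))
      RNifti::writeNifti(nifti_with_voxels(rel, vx),
                         file.path(out_dir,
                                   paste0(sid, "_cbf_pctchange.nii.gz")))
    }
    write_config_echo(out_dir, design, acq, config, shape)
  }
  list(metrics = metrics, report = report, fitness = cohort$fitness)
}
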