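nifti_with_voxels <- function(arr, voxel_mm) {
  im <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(im) <- if (nd == 4) c(voxel_mm, 1) else voxel_mm
  im
}

#' Write an ASL session to disk
#'
#' Emits NIfTI-1 volumes (gzipped) for the control/tag series, M0 and, when
#' ground truth is attached, the tissue partial-volume maps, lobe atlas,
#' lesion/arterial masks and true CBF/ATT maps, with the voxel dimensions on
#' the affine diagonal; acquisition parameters go to a JSON sidecar. Arrays
#' round-trip bit-exactly through [read_dataset()].
#'
#' @param ds An `asl_dataset`.
#' @param directory Output directory (created if needed).
#' @return Data frame manifest (`file`, `kind`), one row per emitted file.
#' @export
write_dataset <- function(ds, directory) {
  stopifnot(inherits(ds, "asl_dataset"))
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  vx <- ds$acq$voxel_mm
  vols <- list(control = ds$control, tag = ds$tag, m0 = ds$m0)
  if (!is.null(ds$truth)) {
    tr <- ds$truth
    vols <- c(vols, list(
      pv_gm = tr$pv_gm, pv_wm = tr$pv_wm, pv_csf = tr$pv_csf,
      lobe_atlas = array(as.double(tr$lobe_atlas), dim(tr$lobe_atlas)),
      lesion_mask = array(as.double(tr$lesion_mask), dim(tr$lesion_mask)),
      arterial_mask = array(as.double(tr$arterial_mask),
                            dim(tr$arterial_mask)),
      cbf_true = tr$cbf_true, att_true = tr$att_true))
  }
  manifest <- list()
  for (nm in names(vols)) {
    f <- file.path(directory, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(nifti_with_voxels(vols[[nm]], vx), f,
                       datatype = "double")
    manifest[[length(manifest) + 1]] <- data.frame(file = basename(f),
                                                   kind = nm,
                                                   stringsAsFactors = FALSE)
  }
  side <- unclass(ds$acq)
  side$subject_id <- ds$subject_id
  side$session_id <- ds$session_id
  f <- file.path(directory, "acq.json")
  jsonlite::write_json(side, f, auto_unbox = TRUE, digits = NA)
  manifest[[length(manifest) + 1]] <- data.frame(file = basename(f),
                                                 kind = "acq",
                                                 stringsAsFactors = FALSE)
  do.call(rbind, manifest)
}

#' Read an ASL session written by [write_dataset()]
#'
#' @param directory Session directory.
#' @return An `asl_dataset`; truth maps are attached when present on disk.
#' @export
read_dataset <- function(directory) {
  rd <- function(nm) {
    f <- file.path(directory, paste0(nm, ".nii.gz"))
    if (!file.exists(f)) return(NULL)
    arr <- as.array(RNifti::readNifti(f))
    attributes(arr) <- list(dim = dim(arr))
    arr
  }
  side <- jsonlite::read_json(file.path(directory, "acq.json"),
                              simplifyVector = TRUE)
  acq <- asl_acquisition(tau_label_ms = side$tau_label_ms,
                         pld0_ms = side$pld0_ms,
                         slice_dt_ms = side$slice_dt_ms,
                         n_slices = side$n_slices,
                         voxel_mm = side$voxel_mm,
                         n_pairs = side$n_pairs,
                         alpha_eff = side$alpha_eff,
                         t1_blood_ms = side$t1_blood_ms,
                         lambda_part = side$lambda_part,
                         fwhm_mm = side$fwhm_mm)
  truth <- NULL
  if (file.exists(file.path(directory, "cbf_true.nii.gz"))) {
    atlas <- rd("lobe_atlas")
    truth <- structure(list(
      cbf_true = rd("cbf_true"), att_true = rd("att_true"),
      pv_gm = rd("pv_gm"), pv_wm = rd("pv_wm"), pv_csf = rd("pv_csf"),
      lobe_atlas = array(as.integer(round(atlas)), dim(atlas)),
      arterial_mask = rd("arterial_mask") > 0.5,
      lesion_mask = rd("lesion_mask") > 0.5,
      brain_mask = (rd("pv_gm") + rd("pv_wm") + rd("pv_csf")) > 0,
      cbf_gm = NA_real_, scov_target_pct = NA_real_,
      att_sd_ms = NA_real_, att_base_ms = NA_real_
    ), class = "asl_truth")
  }
  structure(list(control = rd("control"), tag = rd("tag"), m0 = rd("m0"),
                 acq = acq, truth = truth,
                 subject_id = if (is.null(side$subject_id)) NA_character_
                              else side$subject_id,
                 session_id = if (is.null(side$session_id)) NA_integer_
                              else as.integer(side$session_id)),
            class = "asl_dataset")
}

metrics_required_cols <- c("subject_id", "session_id", "region", "mean_cbf",
                           "scov_pct", "n_voxels")

#' Read a regional-metrics CSV
#'
#' Validates the [roi_metrics()] schema; unknown extra columns are preserved
#' untouched. Malformed rows are rejected with their line numbers.
#'
#' @param path CSV path.
#' @return Data frame in the metrics schema.
#' @export
read_metrics_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(metrics_required_cols, names(tab))
  if (length(miss))
    stop("metrics CSV '", path, "' lacks required column(s): ",
         paste(miss, collapse = ", "))
  for (col in c("mean_cbf", "scov_pct", "n_voxels")) {
    bad <- which(!is.na(tab[[col]]) & !is.finite(suppressWarnings(
      as.numeric(tab[[col]]))))
    if (length(bad))
      stop("metrics CSV '", path, "': non-numeric '", col, "' at line(s) ",
           paste(bad + 1L, collapse = ", "))
    tab[[col]] <- as.numeric(tab[[col]])
  }
  bad <- which(tab$n_voxels < 1)
  if (length(bad))
    stop("metrics CSV '", path, "': n_voxels < 1 at line(s) ",
         paste(bad + 1L, collapse = ", "))
  tab
}

#' Write a regional-metrics CSV
#'
#' @param metrics Data frame in the metrics schema.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  miss <- setdiff(metrics_required_cols, names(metrics))
  if (length(miss))
    stop("metrics table lacks required column(s): ",
         paste(miss, collapse = ", "))
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' Read / write the long-format fitness table
#'
#' Columns: `subject_id`, `months`, `vo2peak`.
#'
#' @param path CSV path. @param fitness Fitness data frame.
#' @return The table (read) or `path` invisibly (write).
#' @export
read_fitness_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("subject_id", "months", "vo2peak"), names(tab))
  if (length(miss))
    stop("fitness CSV '", path, "' lacks required column(s): ",
         paste(miss, collapse = ", "))
  tab
}

#' @rdname read_fitness_csv
#' @export
write_fitness_csv <- function(fitness, path) {
  utils::write.csv(fitness, path, row.names = FALSE)
  invisible(path)
}
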