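#' White-matter internal-standard constants
#'
#' Literature presets used to put DSC maps on an absolute scale: normal
#' white matter is assigned 22 ml/100 g/min (CBF) and 2.7 ml/100 g (CBV).
#'
#' @param wm_cbf,wm_cbv Positive reference values.
#' @return List with `wm_cbf`, `wm_cbv`.
#' @export
calibration_constants <- function(wm_cbf = 22, wm_cbv = 2.7) {
  if (wm_cbf <= 0 || wm_cbv <= 0)
    stop("calibration constants must be > 0", call. = FALSE)
  list(wm_cbf = wm_cbf, wm_cbv = wm_cbv)
}

#' Calibrate perfusion maps to the white-matter internal standard
#'
#' Rescales the CBF and CBV maps so that their means over the white-matter
#' VOI equal the preset constants exactly. The scale factors are recorded in
#' the returned maps.
#'
#' @param maps Uncalibrated `dsc_maps`.
#' @param wm_voi 3D logical array: the white-matter reference VOI (already
#'   intersected with the inclusion mask by the caller).
#' @param constants [calibration_constants()].
#' @return Calibrated `dsc_maps` (`calibrated = TRUE`, `cal_factors` set).
#' @export
calibrate_maps <- function(maps, wm_voi, constants = calibration_constants()) {
  stopifnot(inherits(maps, "dsc_maps"))
  if (isTRUE(maps$calibrated))
    stop("maps are already calibrated", call. = FALSE)
  wm_voi <- mask_data(wm_voi)
  if (!any(wm_voi)) stop("white-matter VOI is empty", call. = FALSE)
  mu_cbf <- mean(maps$cbf[wm_voi])
  mu_cbv <- mean(maps$cbv[wm_voi])
  if (mu_cbf <= 0 || mu_cbv <= 0)
    stop("white-matter mean is not positive; cannot calibrate", call. = FALSE)
  f_cbf <- constants$wm_cbf / mu_cbf
  f_cbv <- constants$wm_cbv / mu_cbv
  maps$cbf <- maps$cbf * f_cbf
  maps$cbv <- maps$cbv * f_cbv
  maps$calibrated <- TRUE
  maps$cal_factors <- c(cbf = f_cbf, cbv = f_cbv)
  maps
}

#' Extract VOI-level perfusion values and white-matter ratios
#'
#' For each labelled structure and side, computes the mean CBF and CBV over
#' the VOI intersected with the inclusion mask, plus the dimensionless
#' ratios rCBF and rCBV against the white-matter reference mean computed on
#' the same inclusion-masked basis. Empty intersections are reported as
#' missing (NA) with a warning, never as zero.
#'
#' @param maps `dsc_maps` (calibrated or not; the ratios are identical).
#' @param label_map 3D integer array aligned with the maps.
#' @param inclusion Inclusion `dsc_mask` (parenchyma AND NOT vessel).
#' @param truths Truth/structure table mapping `label_id` to `name`,
#'   `structure`, `side`; arterial rows are skipped.
#' @param wm_label Label code of the white-matter reference region.
#' @param subject_id,group Identifiers copied into every row.
#' @return A data.frame with one row per structure x side: `subject_id`,
#'   `group`, `structure`, `side`, `n_voxels`, `cbf_mean`, `cbv_mean`,
#'   `rcbf`, `rcbv`.
#' @export
extract_voi_values <- function(maps, label_map, inclusion,
                               truths = tissue_truth_table(),
                               wm_label = PHANTOM_LABELS$white_matter,
                               subject_id = "subject", group = "control") {
  inc <- mask_data(inclusion)
  stopifnot(all(dim(inc) == dim(label_map)))
  wm_sel <- label_map == wm_label & inc
  if (!any(wm_sel))
    stop("white-matter label absent (or fully masked out)", call. = FALSE)
  wm_cbf <- mean(maps$cbf[wm_sel])
  wm_cbv <- mean(maps$cbv[wm_sel])

  rows <- truths[!truths$is_arterial & truths$label_id != wm_label, ]
  lab_inc <- label_map[inc]
  f <- factor(lab_inc, levels = rows$label_id)
  n_vox <- as.integer(table(f))
  cbf_sum <- as.vector(tapply(maps$cbf[inc], f, sum, default = 0))
  cbv_sum <- as.vector(tapply(maps$cbv[inc], f, sum, default = 0))
  cbf <- ifelse(n_vox > 0, cbf_sum / n_vox, NA_real_)
  cbv <- ifelse(n_vox > 0, cbv_sum / n_vox, NA_real_)
  if (any(n_vox == 0L))
    warning(sprintf("VOI(s) empty after masking for subject %s: %s",
                    subject_id,
                    paste(rows$name[n_vox == 0L], collapse = ", ")))
  data.frame(subject_id = subject_id, group = group,
             structure = rows$structure, side = rows$side,
             n_voxels = n_vox, cbf_mean = cbf, cbv_mean = cbv,
             rcbf = cbf / wm_cbf, rcbv = cbv / wm_cbv,
             stringsAsFactors = FALSE, row.names = NULL)
}
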