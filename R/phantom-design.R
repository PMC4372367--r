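#' Acquisition parameters for a DSC-MRI series
#'
#' Bundles the timing and geometry of a dynamic susceptibility contrast
#' acquisition. Defaults emulate a 1.5 T gradient-echo EPI perfusion series
#' (TR 1.5 s, TE 46 ms, ~90 s of sampling) on a compact phantom matrix.
#'
#' @param tr Repetition time, seconds per timepoint.
#' @param te Echo time, seconds.
#' @param n_timepoints Number of dynamic volumes (>= 10).
#' @param matrix_shape Integer vector of 3 voxel counts (x, y, z).
#' @param voxel_size Voxel edge lengths in mm.
#' @return An object of class `dsc_acq`.
#' @export
acquisition_params <- function(tr = 1.5, te = 0.046, n_timepoints = 60L,
                               matrix_shape = c(48L, 48L, 12L),
                               voxel_size = c(4.8, 4.8, 6.0)) {
  stopifnot(is.numeric(tr), length(tr) == 1L, is.numeric(te), length(te) == 1L)
  if (tr <= 0) stop("`tr` must be > 0", call. = FALSE)
  if (te <= 0) stop("`te` must be > 0", call. = FALSE)
  n_timepoints <- as.integer(n_timepoints)
  if (n_timepoints < 10L) stop("`n_timepoints` must be >= 10", call. = FALSE)
  matrix_shape <- as.integer(matrix_shape)
  if (length(matrix_shape) != 3L || any(matrix_shape < 1L))
    stop("`matrix_shape` must be 3 positive voxel counts", call. = FALSE)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be 3 positive lengths (mm)", call. = FALSE)
  structure(
    list(tr = tr, te = te, n_timepoints = n_timepoints,
         matrix_shape = matrix_shape, voxel_size = voxel_size,
         t_axis = (seq_len(n_timepoints) - 1) * tr),
    class = "dsc_acq"
  )
}

#' Structure codes used in phantom label maps
#'
#' Named list of integer label codes. Right-side codes end in 1, left in 2;
#' white matter, artery and background have scalar codes.
#' @export
PHANTOM_LABELS <- list(
  background = 0L, white_matter = 7L, artery = 8L,
  amygdala_r = 11L, amygdala_l = 12L,
  hippocampus_r = 21L, hippocampus_l = 22L,
  thalamus_r = 31L, thalamus_l = 32L,
  putamen_r = 41L, putamen_l = 42L,
  globus_pallidus_r = 51L, globus_pallidus_l = 52L,
  caudate_r = 61L, caudate_l = 62L
)

#' Ground-truth tissue table for the digital perfusion phantom
#'
#' One row per labelled region with true CBF (ml/100 g/min), CBV (ml/100 g),
#' MTT (s, by the central volume theorem MTT = 60*CBV/CBF), baseline signal
#' and an arterial flag. White matter carries the internal-standard values
#' (22 ml/100 g/min, 2.7 ml/100 g); subcortical structures carry deep
#' gray-matter values from the PET literature, which run lower than cortical
#' gray matter.
#'
#' @param wm_cbf,wm_cbv White-matter reference perfusion values.
#' @param s0 Baseline (pre-bolus) signal intensity, arbitrary units.
#' @return A data.frame of class `dsc_truth` with columns `label_id`, `name`,
#'   `structure`, `side`, `cbf_true`, `cbv_true`, `mtt_true`, `s0`,
#'   `is_arterial`.
#' @export
tissue_truth_table <- function(wm_cbf = 22, wm_cbv = 2.7, s0 = 1000) {
  gm <- data.frame(
    structure = c("amygdala", "hippocampus", "thalamus", "putamen",
                  "globus_pallidus", "caudate"),
    cbf = c(46, 48, 58, 55, 42, 52),
    cbv = c(3.5, 3.6, 4.1, 4.0, 3.2, 3.8),
    stringsAsFactors = FALSE
  )
  rows <- do.call(rbind, lapply(seq_len(nrow(gm)), function(i) {
    data.frame(
      name = paste0(gm$structure[i], c("_r", "_l")),
      structure = gm$structure[i], side = c("right", "left"),
      cbf_true = gm$cbf[i], cbv_true = gm$cbv[i],
      stringsAsFactors = FALSE
    )
  }))
  rows <- rbind(
    data.frame(name = "white_matter", structure = "white_matter", side = "both",
               cbf_true = wm_cbf, cbv_true = wm_cbv, stringsAsFactors = FALSE),
    rows,
    # nominal whole-blood values; arterial voxels carry the AIF directly
    data.frame(name = "artery", structure = "artery", side = "both",
               cbf_true = 4000, cbv_true = 100, stringsAsFactors = FALSE)
  )
  rows$label_id <- vapply(rows$name, function(nm) PHANTOM_LABELS[[nm]], integer(1))
  rows$mtt_true <- 60 * rows$cbv_true / rows$cbf_true
  rows$s0 <- s0
  rows$is_arterial <- rows$structure == "artery"
  rownames(rows) <- NULL
  stopifnot(all(rows$cbf_true >= 0), all(rows$cbv_true >= 0),
            all(rows$mtt_true[rows$cbf_true > 0] > 0))
  structure(rows[, c("label_id", "name", "structure", "side", "cbf_true",
                     "cbv_true", "mtt_true", "s0", "is_arterial")],
            class = c("dsc_truth", "data.frame"))
}

#' Cohort design for a matched patient/control simulation
#'
#' Defines a cohort of `n_patients` patients, each matched to
#' `controls_per_patient` controls, with a multiplicative CBF/CBV reduction
#' (`effect_fraction`) applied to the patients' `effect_regions`.
#'
#' @param n_patients Number of patients.
#' @param controls_per_patient Matched controls per patient (>= 1).
#' @param effect_regions Character vector of truth-table region names whose
#'   patient CBF and CBV are multiplied by `effect_fraction`.
#' @param effect_fraction Multiplicative reduction in (0, 1]; 1 = null cohort.
#' @param noise_sigma Gaussian noise SD on the signal, same units as `s0`.
#' @param seed Integer RNG seed; per-subject seeds are derived from it.
#' @return An object of class `dsc_cohort_design`.
#' @export
cohort_design <- function(n_patients = 5L, controls_per_patient = 3L,
                          effect_regions = c("hippocampus_r", "hippocampus_l"),
                          effect_fraction = 0.8, noise_sigma = 20, seed = 1L) {
  n_patients <- as.integer(n_patients)
  controls_per_patient <- as.integer(controls_per_patient)
  if (n_patients < 1L) stop("`n_patients` must be >= 1", call. = FALSE)
  if (controls_per_patient < 1L)
    stop("`controls_per_patient` must be >= 1", call. = FALSE)
  if (!(effect_fraction > 0 && effect_fraction <= 1))
    stop("`effect_fraction` must be in (0, 1]", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  structure(
    list(n_patients = n_patients, controls_per_patient = controls_per_patient,
         effect_regions = effect_regions, effect_fraction = effect_fraction,
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "dsc_cohort_design"
  )
}

# Phantom geometry: an ellipsoidal head of white matter containing six
# bilateral subcortical boxes and a vertical arterial column. Positions are
# fractions of the matrix so the layout scales with `matrix_shape`.
phantom_label_map <- function(matrix_shape) {
  nx <- matrix_shape[1]; ny <- matrix_shape[2]; nz <- matrix_shape[3]
  lab <- array(PHANTOM_LABELS$background, dim = c(nx, ny, nz))
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  rx <- 0.42 * nx; ry <- 0.42 * ny; rz <- 0.42 * nz
  idx <- expand.grid(x = seq_len(nx), y = seq_len(ny), z = seq_len(nz))
  inside <- ((idx$x - cx) / rx)^2 + ((idx$y - cy) / ry)^2 + ((idx$z - cz) / rz)^2 <= 1
  lab[as.matrix(idx[inside, ])] <- PHANTOM_LABELS$white_matter

  box <- function(fx, fy, fz, hw) {
    xr <- max(1L, round(fx * nx) - hw[1]):min(nx, round(fx * nx) + hw[1])
    yr <- max(1L, round(fy * ny) - hw[2]):min(ny, round(fy * ny) + hw[2])
    zr <- max(1L, round(fz * nz) - hw[3]):min(nz, round(fz * nz) + hw[3])
    as.matrix(expand.grid(x = xr, y = yr, z = zr))
  }
  structs <- c("amygdala", "hippocampus", "thalamus", "putamen",
               "globus_pallidus", "caudate")
  fy <- seq(0.22, 0.78, length.out = 6)
  gap <- (fy[2] - fy[1]) * ny
  # keep boxes disjoint in y at any matrix size
  hw <- c(round(nx / 24), min(round(ny / 24), floor((gap - 1) / 2)),
          round(nz / 12))
  hw <- pmax(0L, as.integer(hw))
  for (i in seq_along(structs)) {
    lab[box(0.35, fy[i], 0.5, hw)] <- PHANTOM_LABELS[[paste0(structs[i], "_r")]]
    lab[box(0.65, fy[i], 0.5, hw)] <- PHANTOM_LABELS[[paste0(structs[i], "_l")]]
  }
  # arterial column: small cross-section, spans the central two thirds of z
  ahw <- max(0L, round(nx / 48))
  zr <- max(1L, round(nz / 6)):min(nz, round(5 * nz / 6))
  xr <- (round(0.5 * nx) - ahw):(round(0.5 * nx) + ahw)
  yr <- (round(0.16 * ny) - ahw):(round(0.16 * ny) + ahw)
  lab[as.matrix(expand.grid(x = xr, y = yr, z = zr))] <- PHANTOM_LABELS$artery
  lab
}

# Anatomical intensities by label: background 0, WM 200, GM 300, artery 400.
phantom_anatomical <- function(label_map) {
  anat <- array(0, dim = dim(label_map))
  anat[label_map == PHANTOM_LABELS$white_matter] <- 200
  anat[label_map >= 10L] <- 300
  anat[label_map == PHANTOM_LABELS$artery] <- 400
  anat
}
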