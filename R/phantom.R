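#' Gamma-variate bolus curve
#'
#' Standard first-pass bolus model
#' \eqn{C(t) = A \cdot (t - t_0)^\alpha \exp(-(t - t_0)/\beta)} for
#' \eqn{t > t_0}, zero before arrival, rescaled so its peak equals
#' `amplitude`. The analytic peak sits at \eqn{t_0 + \alpha\beta}.
#'
#' @param t_axis Nondecreasing time axis, seconds.
#' @param t0 Bolus arrival time, seconds.
#' @param alpha Shape parameter (> 0).
#' @param beta Time-scale parameter, seconds (> 0).
#' @param amplitude Peak concentration, arbitrary units (>= 0).
#' @return Numeric concentration curve along `t_axis`.
#' @export
gamma_variate_curve <- function(t_axis, t0, alpha, beta, amplitude) {
  if (alpha <= 0 || beta <= 0)
    stop("`alpha` and `beta` must be > 0", call. = FALSE)
  if (amplitude < 0) stop("`amplitude` must be >= 0", call. = FALSE)
  if (is.unsorted(t_axis)) stop("`t_axis` must be nondecreasing", call. = FALSE)
  y <- numeric(length(t_axis))
  up <- t_axis > t0
  tt <- t_axis[up] - t0
  peak <- (alpha * beta)^alpha * exp(-alpha)
  y[up] <- amplitude * tt^alpha * exp(-tt / beta) / peak
  y
}

# Bolus shape defaults: canonical simulation AIF (alpha = 3, beta = 1.5 s)
# arriving 10 s into the acquisition; recirculation as a delayed, dispersed
# gamma-variate at 30% of first-pass amplitude. The amplitude is set so that
# at TE = 46 ms the arterial signal drops by ~84% and tissue by a few
# percent, the regime of a real gradient-echo DSC acquisition.
bolus_params <- function(t0 = 10, alpha = 3, beta = 1.5, amplitude = 40,
                         recirc_delay = 22, recirc_dispersion = 2,
                         recirc_fraction = 0.3) {
  list(t0 = t0, alpha = alpha, beta = beta, amplitude = amplitude,
       recirc_delay = recirc_delay, recirc_dispersion = recirc_dispersion,
       recirc_fraction = recirc_fraction)
}

# Arterial concentration (first pass + recirculation) on an arbitrary grid.
phantom_aif_curve <- function(t_axis, bolus = bolus_params(),
                              recirculation = TRUE) {
  first <- gamma_variate_curve(t_axis, bolus$t0, bolus$alpha, bolus$beta,
                               bolus$amplitude)
  if (!recirculation) return(first)
  first + gamma_variate_curve(t_axis, bolus$t0 + bolus$recirc_delay,
                              bolus$alpha,
                              bolus$beta * bolus$recirc_dispersion,
                              bolus$amplitude * bolus$recirc_fraction)
}

#' Synthesize a tissue concentration curve from an AIF
#'
#' Indicator-dilution forward model: the tissue curve is
#' \eqn{C_t(t) = (CBF/6000) \int AIF(\tau) R(t-\tau) d\tau}, evaluated as a
#' dt-scaled discrete convolution with a residue function R(t) (R(0) = 1,
#' monotone nonincreasing). The 6000 converts ml/100 g/min to 1/s per gram
#' of tissue, so the curve integral over the AIF integral equals CBV/100.
#'
#' @param aif_true Arterial concentration curve, sampled at spacing `dt`.
#' @param cbf_true True CBF, ml/100 g/min (>= 0).
#' @param mtt_true True mean transit time, seconds.
#' @param dt Sampling interval of `aif_true`, seconds.
#' @param residue_model `"exponential"` (R(t) = exp(-t/MTT)) or `"boxcar"`
#'   (R(t) = 1 for t < MTT).
#' @return Tissue concentration curve, same length as `aif_true`.
#' @export
synthesize_tissue_curve <- function(aif_true, cbf_true, mtt_true, dt,
                                    residue_model = c("exponential", "boxcar")) {
  residue_model <- match.arg(residue_model)
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  if (cbf_true < 0) stop("`cbf_true` must be >= 0", call. = FALSE)
  n <- length(aif_true)
  if (cbf_true == 0) return(numeric(n))
  # discrete convolution sum_j aif[j] R[(i-j)*dt], computed in O(n):
  # exponential residue -> first-order recursive filter; boxcar -> rolling sum
  conv <- switch(residue_model,
    exponential = as.vector(stats::filter(aif_true, exp(-dt / mtt_true),
                                          method = "recursive")),
    boxcar = {
      k <- sum((seq_len(n) - 1) * dt < mtt_true)
      cs <- cumsum(aif_true)
      cs - c(rep(0, k), cs[seq_len(n - k)])
    }
  )
  (cbf_true / 6000) * dt * conv
}

#' Generate one synthetic DSC-MRI study
#'
#' Builds the phantom label map and anatomical volume, synthesizes per-region
#' concentration curves on a fine internal time grid (first-pass +
#' recirculation AIF convolved with exponential residues), samples them at
#' TR, converts to signal via \eqn{S(t) = S_0 \exp(-TE \cdot k \cdot C(t))}
#' (k = 1, arbitrary concentration units) and adds Gaussian signal noise.
#' Arterial voxels carry the undispersed AIF, giving them the highest Cmax
#' and earliest TTP in the volume.
#'
#' @param acq An [acquisition_params()] object.
#' @param truths A [tissue_truth_table()] data.frame.
#' @param noise_sigma Gaussian noise SD on the signal (>= 0).
#' @param seed Integer seed; identical seeds give bit-identical studies.
#' @param bolus Bolus shape parameters from `bolus_params()`.
#' @param fine_dt Internal synthesis grid spacing, seconds.
#' @param template Optional precomputed [study_template()] (must match
#'   `acq`, `truths` and `bolus`); avoids recomputing the noise-free part
#'   for every noise realization.
#' @return A list of class `dsc_study` with elements `signal` (4D array),
#'   `anatomical`, `label_map`, `truth_maps` (list of 3D `cbf`, `cbv`),
#'   `conc_true` (matrix of noise-free regional concentration curves),
#'   `aif_true` (first-pass-only arterial curve at TR), `acq`, `truths`.
#' @export
generate_study <- function(acq, truths = tissue_truth_table(),
                           noise_sigma = 0, seed = NULL,
                           bolus = bolus_params(), fine_dt = 0.05,
                           template = NULL) {
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (is.null(template))
    template <- study_template(acq, truths, bolus, fine_dt)
  signal <- template$signal_clean
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (noise_sigma > 0)
    signal <- signal + stats::rnorm(length(signal), sd = noise_sigma)
  signal <- array(signal, dim = c(acq$matrix_shape, acq$n_timepoints))

  structure(
    list(signal = signal, anatomical = template$anatomical,
         label_map = template$label_map, truth_maps = template$truth_maps,
         conc_true = template$conc_true, aif_true = template$aif_true,
         acq = acq, truths = truths, bolus = bolus,
         noise_sigma = noise_sigma, seed = seed),
    class = "dsc_study"
  )
}

#' Precompute the noise-free part of a synthetic study
#'
#' Builds the label map, anatomical volume, regional noise-free
#' concentration curves and clean signal matrix for a given truth table.
#' Pass the result as `template` to [generate_study()] to amortize this work
#' over many noise realizations (e.g. cohort simulation).
#'
#' @inheritParams generate_study
#' @return List with `label_map`, `anatomical`, `truth_maps`, `conc_true`,
#'   `aif_true`, `signal_clean`.
#' @export
study_template <- function(acq, truths = tissue_truth_table(),
                           bolus = bolus_params(), fine_dt = 0.05) {
  label_map <- phantom_label_map(acq$matrix_shape)
  anatomical <- phantom_anatomical(label_map)
  ids <- sort(unique(as.vector(label_map)))
  miss <- setdiff(ids, c(0L, truths$label_id))
  if (length(miss) > 0)
    stop("label map contains ids missing from the truth table: ",
         paste(miss, collapse = ", "), call. = FALSE)

  # fine-grid synthesis, sampled at TR (a TR-grid rectangle convolution
  # would inflate CBV by an MTT-dependent discretization bias)
  t_fine <- seq(0, max(acq$t_axis), by = fine_dt)
  samp_idx <- round(acq$t_axis / fine_dt) + 1
  aif_fine <- phantom_aif_curve(t_fine, bolus)
  conc_true <- matrix(0, nrow = acq$n_timepoints, ncol = length(ids),
                      dimnames = list(NULL, as.character(ids)))
  for (id in setdiff(ids, 0L)) {
    row <- truths[truths$label_id == id, ]
    curve <- if (row$is_arterial) {
      aif_fine
    } else {
      synthesize_tissue_curve(aif_fine, row$cbf_true, row$mtt_true, fine_dt)
    }
    conc_true[, as.character(id)] <- curve[samp_idx]
  }

  nvox <- prod(acq$matrix_shape)
  lab_vec <- as.vector(label_map)
  s0_vec <- rep(10, nvox)  # dim background signal; masked out downstream
  conc_mat <- matrix(0, nrow = nvox, ncol = acq$n_timepoints)
  for (id in setdiff(ids, 0L)) {
    row <- truths[truths$label_id == id, ]
    sel <- lab_vec == id
    s0_vec[sel] <- row$s0
    conc_mat[sel, ] <- matrix(conc_true[, as.character(id)], sum(sel),
                              acq$n_timepoints, byrow = TRUE)
  }
  signal_clean <- s0_vec * exp(-acq$te * conc_mat)

  truth_maps <- list(
    cbf = array(0, dim = acq$matrix_shape),
    cbv = array(0, dim = acq$matrix_shape)
  )
  for (id in setdiff(ids, 0L)) {
    row <- truths[truths$label_id == id, ]
    truth_maps$cbf[label_map == id] <- row$cbf_true
    truth_maps$cbv[label_map == id] <- row$cbv_true
  }

  list(label_map = label_map, anatomical = anatomical,
       truth_maps = truth_maps, conc_true = conc_true,
       aif_true = phantom_aif_curve(t_fine, bolus,
                                    recirculation = FALSE)[samp_idx],
       signal_clean = signal_clean)
}

#' Generate a matched patient/control cohort of synthetic studies
#'
#' Patients have `cbf_true` and `cbv_true` multiplied by
#' `design$effect_fraction` in `design$effect_regions` (MTT is unchanged,
#' preserving central-volume consistency); controls use the unmodified truth
#' table. Per-subject seeds are derived deterministically from `design$seed`.
#'
#' @param design A [cohort_design()] object.
#' @param acq An [acquisition_params()] object.
#' @param truths Baseline truth table.
#' @param materialize If `TRUE` (default) each subject carries a generated
#'   `dsc_study`; if `FALSE` only the per-subject plan (truths, seed, group)
#'   is returned, for memory-lean streaming.
#' @return List of subjects, each a list with `subject_id`, `group`,
#'   `seed`, `truths`, and (if materialized) `study`.
#' @export
generate_cohort <- function(design, acq, truths = tissue_truth_table(),
                            materialize = TRUE) {
  stopifnot(inherits(design, "dsc_cohort_design"))
  bad <- setdiff(design$effect_regions, truths$name)
  if (length(bad) > 0)
    stop("effect regions not in the truth table: ",
         paste(bad, collapse = ", "), call. = FALSE)
  patient_truths <- truths
  sel <- patient_truths$name %in% design$effect_regions
  patient_truths$cbf_true[sel] <- patient_truths$cbf_true[sel] * design$effect_fraction
  patient_truths$cbv_true[sel] <- patient_truths$cbv_true[sel] * design$effect_fraction

  n_controls <- design$n_patients * design$controls_per_patient
  groups <- c(rep("patient", design$n_patients), rep("control", n_controls))
  subjects <- lapply(seq_along(groups), function(i) {
    subj <- list(
      subject_id = sprintf("%s%02d", ifelse(groups[i] == "patient", "P", "C"),
                           ifelse(groups[i] == "patient", i,
                                  i - design$n_patients)),
      group = groups[i],
      seed = subject_seed(design$seed, i),
      truths = if (groups[i] == "patient") patient_truths else truths
    )
    if (materialize)
      subj$study <- generate_study(acq, subj$truths,
                                   noise_sigma = design$noise_sigma,
                                   seed = subj$seed)
    subj
  })
  subjects
}

# deterministic per-subject seed, kept within 32-bit integer range
subject_seed <- function(base_seed, i) {
  as.integer((as.double(base_seed) + 7919 * i) %% 2147483647)
}
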