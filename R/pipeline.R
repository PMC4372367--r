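#' Pipeline configuration
#'
#' Collects every tunable of the quantification pipeline with its default.
#'
#' @param baseline_window Baseline timepoint indices, or `NULL` to detect.
#' @param n_aif Number of AIF voxels to average.
#' @param aif_smooth_window Odd moving-average width for the AIF.
#' @param aif_truncate Truncate the AIF after the first pass.
#' @param svd_threshold SVD truncation fraction of the largest singular
#'   value.
#' @param vessel_factor Vessel threshold as a multiple of the median
#'   parenchymal Cmax.
#' @param constants White-matter calibration constants.
#' @param stats_mode Test mode for the group analysis.
#' @param alpha Significance level.
#' @return List of class `dsc_config`.
#' @export
pipeline_config <- function(baseline_window = NULL, n_aif = 20L,
                            aif_smooth_window = 3L, aif_truncate = TRUE,
                            svd_threshold = 0.2, vessel_factor = 3.0,
                            constants = calibration_constants(),
                            stats_mode = "auto", alpha = 0.05) {
  structure(
    list(baseline_window = baseline_window, n_aif = as.integer(n_aif),
         aif_smooth_window = as.integer(aif_smooth_window),
         aif_truncate = aif_truncate, svd_threshold = svd_threshold,
         vessel_factor = vessel_factor, constants = constants,
         stats_mode = stats_mode, alpha = alpha),
    class = "dsc_config"
  )
}

#' Quantify one study end-to-end
#'
#' Chains signal-to-concentration conversion, parenchyma masking, descriptor
#' maps, automatic AIF selection, SVD deconvolution, vessel/inclusion
#' masking, white-matter calibration and VOI extraction. The AIF search
#' space is the whole parenchyma mask (which still contains vessels; that is
#' where the arteries are).
#'
#' @param study A `dsc_study` or a list with `signal`, `anatomical`,
#'   `label_map`, `acq` (and optionally `truths`).
#' @param config A [pipeline_config()].
#' @param subject_id,group Identifiers for the VOI rows.
#' @param parenchyma Optional precomputed parenchyma `dsc_mask` (e.g. when
#'   quantifying many studies that share one anatomical volume); computed
#'   from `study$anatomical` when `NULL`.
#' @return List with `maps` (calibrated), `aif`, `masks` (parenchyma,
#'   vessel, inclusion), `descriptors`, `voi` (data.frame), `manifest`.
#' @export
quantify_study <- function(study, config = pipeline_config(),
                           subject_id = "subject", group = "control",
                           parenchyma = NULL) {
  truths <- if (!is.null(study$truths)) study$truths else tissue_truth_table()
  if (is.null(parenchyma)) parenchyma <- parenchyma_mask(study$anatomical)
  conc <- signal_to_concentration(study, config$baseline_window,
                                  mask = parenchyma$data)
  desc <- descriptor_maps(conc, mask = parenchyma$data)
  cands <- rank_aif_candidates(desc, parenchyma$data)
  aif <- build_aif(conc, cands, n = config$n_aif,
                   smooth_window = config$aif_smooth_window,
                   truncate = config$aif_truncate)
  maps <- make_maps(conc, aif, parenchyma$data,
                    svd_threshold = config$svd_threshold)
  vessel <- vessel_mask(desc$cmax, parenchyma, factor = config$vessel_factor)
  inclusion <- inclusion_mask(parenchyma, vessel)
  wm_voi <- study$label_map == PHANTOM_LABELS$white_matter & inclusion$data
  maps <- calibrate_maps(maps, wm_voi, config$constants)
  voi <- extract_voi_values(maps, study$label_map, inclusion, truths,
                            subject_id = subject_id, group = group)
  list(
    maps = maps, aif = aif,
    masks = list(parenchyma = parenchyma, vessel = vessel,
                 inclusion = inclusion),
    descriptors = desc, voi = voi,
    manifest = list(
      subject_id = subject_id, group = group,
      baseline_window = conc$baseline_window,
      n_clipped = conc$n_clipped,
      aif_truncation_index = aif$truncation_index,
      n_parenchyma = sum(parenchyma$data), n_vessel = sum(vessel$data),
      n_included = sum(inclusion$data),
      cal_factors = maps$cal_factors,
      svd_threshold = config$svd_threshold,
      vessel_factor = config$vessel_factor
    )
  )
}

#' Run a cohort simulation and analysis fully in memory
#'
#' Generates each subject of the design, quantifies it, stacks the VOI
#' tables and runs the group/laterality comparison. Subjects are processed
#' one at a time so only one 4D volume is in memory at once.
#'
#' @param design A [cohort_design()].
#' @param acq An [acquisition_params()].
#' @param config A [pipeline_config()].
#' @param truths Baseline truth table.
#' @return List with `voi` (all subjects) and `results`
#'   (`dsc_comparison`).
#' @export
run_cohort_analysis <- function(design, acq, config = pipeline_config(),
                                truths = tissue_truth_table()) {
  plans <- generate_cohort(design, acq, truths, materialize = FALSE)
  # anatomy and noise-free curves are shared within each group, so the
  # study template and its segmentation are computed once per group
  templates <- list(
    patient = study_template(acq, plans[[1]]$truths),
    control = study_template(acq, plans[[length(plans)]]$truths)
  )
  parenchyma <- parenchyma_mask(templates$control$anatomical)
  voi <- do.call(rbind, lapply(plans, function(p) {
    study <- generate_study(acq, p$truths, noise_sigma = design$noise_sigma,
                            seed = p$seed, template = templates[[p$group]])
    quantify_study(study, config, subject_id = p$subject_id,
                   group = p$group, parenchyma = parenchyma)$voi
  }))
  list(voi = voi,
       results = run_group_analysis(voi, alpha = config$alpha,
                                    mode = config$stats_mode))
}
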