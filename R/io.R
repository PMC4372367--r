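#' Write a study to a directory as NIfTI volumes with JSON sidecar
#'
#' Writes `series.nii.gz` (4D signal), `anatomical.nii.gz`,
#' `labels.nii.gz` (integer label map), `truth_cbf.nii.gz`,
#' `truth_cbv.nii.gz` and `study.json` (acquisition parameters, truth
#' table, seed, noise level).
#'
#' @param study A `dsc_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- study$acq$voxel_size
  wr <- function(x, name) {
    img <- RNifti::asNifti(x)
    RNifti::pixdim(img) <- c(vs, study$acq$tr)[seq_len(length(dim(x)))]
    RNifti::writeNifti(img, file.path(dir, paste0(name, ".nii.gz")))
  }
  wr(study$signal, "series")
  wr(study$anatomical, "anatomical")
  wr(study$label_map, "labels")
  wr(study$truth_maps$cbf, "truth_cbf")
  wr(study$truth_maps$cbv, "truth_cbv")
  sidecar <- list(
    acq = study$acq[c("tr", "te", "n_timepoints", "matrix_shape",
                      "voxel_size")],
    truths = as.data.frame(study$truths),
    noise_sigma = study$noise_sigma,
    seed = study$seed
  )
  jsonlite::write_json(sidecar, file.path(dir, "study.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#'
#' @param dir Study directory.
#' @return A `dsc_study`-compatible list (without noise-free regional
#'   curves, which are not stored).
#' @export
read_study <- function(dir) {
  sc_path <- file.path(dir, "study.json")
  if (!file.exists(sc_path))
    stop("not a study directory (missing study.json): ", dir, call. = FALSE)
  sidecar <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  acq <- acquisition_params(
    tr = sidecar$acq$tr, te = sidecar$acq$te,
    n_timepoints = sidecar$acq$n_timepoints,
    matrix_shape = sidecar$acq$matrix_shape,
    voxel_size = sidecar$acq$voxel_size
  )
  rd <- function(name) {
    f <- file.path(dir, paste0(name, ".nii.gz"))
    if (!file.exists(f)) stop("missing input volume: ", f, call. = FALSE)
    arr <- as.array(RNifti::readNifti(f))
    attributes(arr) <- list(dim = dim(arr))
    arr
  }
  truths <- sidecar$truths
  class(truths) <- c("dsc_truth", "data.frame")
  structure(
    list(signal = rd("series"), anatomical = rd("anatomical"),
         label_map = array(as.integer(rd("labels")),
                           dim = acq$matrix_shape),
         truth_maps = list(cbf = rd("truth_cbf"), cbv = rd("truth_cbv")),
         acq = acq, truths = truths,
         noise_sigma = sidecar$noise_sigma, seed = sidecar$seed),
    class = "dsc_study"
  )
}

#' Write quantification outputs for one subject
#'
#' Writes CBF/CBV maps, descriptor maps (Cmax, TTP, fMTT) and masks as
#' NIfTI, the AIF as a two-column CSV plus a JSON record of its voxel
#' indices and truncation index, the VOI table as CSV, and the run manifest
#' as JSON.
#'
#' @param result Output of [quantify_study()].
#' @param dir Output directory.
#' @param acq Acquisition parameters (for voxel sizes).
#' @return `dir`, invisibly.
#' @export
write_quantification <- function(result, dir, acq) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    img <- RNifti::asNifti(x)
    RNifti::pixdim(img) <- acq$voxel_size
    RNifti::writeNifti(img, file.path(dir, paste0(name, ".nii.gz")))
  }
  wr(result$maps$cbf, "cbf")
  wr(result$maps$cbv, "cbv")
  wr(result$descriptors$cmax, "cmax")
  wr(result$descriptors$ttp, "ttp")
  wr(result$descriptors$fmtt, "fmtt")
  wr(array(as.integer(result$masks$parenchyma$data),
           dim(result$masks$parenchyma$data)), "mask_parenchyma")
  wr(array(as.integer(result$masks$vessel$data),
           dim(result$masks$vessel$data)), "mask_vessel")
  wr(array(as.integer(result$masks$inclusion$data),
           dim(result$masks$inclusion$data)), "mask_inclusion")
  utils::write.csv(
    data.frame(time = result$aif$t_axis, concentration = result$aif$curve),
    file.path(dir, "aif.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(voxel_indices = result$aif$voxel_indices,
         n_selected = result$aif$n_selected,
         truncation_index = result$aif$truncation_index),
    file.path(dir, "aif.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(result$voi, file.path(dir, "voi.csv"), row.names = FALSE)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Simulate a cohort to disk
#'
#' Writes one subdirectory per subject (`P01`, ..., `C01`, ...) containing
#' the study volumes, plus a cohort-level `cohort.json` manifest with the
#' design, seeds and group labels.
#'
#' @param design A [cohort_design()].
#' @param acq An [acquisition_params()].
#' @param out_dir Output directory.
#' @param truths Baseline truth table.
#' @return `out_dir`, invisibly.
#' @export
simulate_cohort <- function(design, acq, out_dir,
                            truths = tissue_truth_table()) {
  plans <- generate_cohort(design, acq, truths, materialize = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (p in plans) {
    study <- generate_study(acq, p$truths, noise_sigma = design$noise_sigma,
                            seed = p$seed)
    write_study(study, file.path(out_dir, p$subject_id))
  }
  manifest <- list(
    design = unclass(design),
    acq = acq[c("tr", "te", "n_timepoints", "matrix_shape", "voxel_size")],
    subjects = data.frame(
      subject_id = vapply(plans, `[[`, "", "subject_id"),
      group = vapply(plans, `[[`, "", "group"),
      seed = vapply(plans, `[[`, integer(1), "seed")
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Quantify every subject of a simulated cohort directory
#'
#' @param cohort_dir Directory written by [simulate_cohort()].
#' @param config A [pipeline_config()].
#' @return Combined VOI data.frame over all subjects (also written as
#'   `voi_all.csv` in `cohort_dir`).
#' @export
quantify_cohort_dir <- function(cohort_dir, config = pipeline_config()) {
  manifest <- jsonlite::read_json(file.path(cohort_dir, "cohort.json"),
                                  simplifyVector = TRUE)
  subjects <- manifest$subjects
  voi <- do.call(rbind, lapply(seq_len(nrow(subjects)), function(i) {
    sdir <- file.path(cohort_dir, subjects$subject_id[i])
    study <- read_study(sdir)
    res <- quantify_study(study, config,
                          subject_id = subjects$subject_id[i],
                          group = subjects$group[i])
    write_quantification(res, file.path(sdir, "quant"), study$acq)
    res$voi
  }))
  utils::write.csv(voi, file.path(cohort_dir, "voi_all.csv"),
                   row.names = FALSE)
  voi
}

#' Compare the groups of a quantified cohort directory
#'
#' Reads `voi_all.csv`, runs [run_group_analysis()], and writes
#' `results.csv` plus a markdown `results.md` table.
#'
#' @param cohort_dir Quantified cohort directory.
#' @param config A [pipeline_config()].
#' @return The `dsc_comparison` data.frame.
#' @export
compare_cohort_dir <- function(cohort_dir, config = pipeline_config()) {
  f <- file.path(cohort_dir, "voi_all.csv")
  if (!file.exists(f))
    stop("no voi_all.csv in ", cohort_dir, "; run quantify first",
         call. = FALSE)
  voi <- utils::read.csv(f, stringsAsFactors = FALSE)
  if (length(unique(voi$group)) < 2L)
    stop("cohort contains a single group; nothing to compare", call. = FALSE)
  results <- run_group_analysis(voi, alpha = config$alpha,
                                mode = config$stats_mode)
  utils::write.csv(as.data.frame(results),
                   file.path(cohort_dir, "results.csv"), row.names = FALSE)
  writeLines(c(format_comparison_table(results, "rcbf"), "",
               format_comparison_table(results, "rcbv")),
             file.path(cohort_dir, "results.md"))
  results
}
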