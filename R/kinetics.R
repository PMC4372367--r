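#' Convert a dynamic signal series to contrast concentration
#'
#' Inverts the single-exponential DSC susceptibility relation: per voxel,
#' \eqn{S_0} is the mean signal over the baseline window and
#' \eqn{C(t) = -\ln(S(t)/S_0) / (TE \cdot k)} with the internal unit
#' constant k = 1 (concentrations are in arbitrary units; k cancels in all
#' reported ratios). Non-positive signal samples are mapped to C = 0 and
#' counted.
#'
#' @param study A `dsc_study`, or a list with a 4D `signal` array and an
#'   `acq` of class `dsc_acq`.
#' @param baseline_window Integer vector of timepoint indices used for S0;
#'   `NULL` to auto-detect with [detect_baseline_window()].
#' @param mask Optional 3D logical array; baseline validity is only enforced
#'   (and an error raised) for in-mask voxels.
#' @return Object of class `dsc_conc`: 4D `data` array, `t_axis`,
#'   `baseline_window`, `n_clipped` count of non-positive signal samples.
#' @export
signal_to_concentration <- function(study, baseline_window = NULL,
                                    mask = NULL) {
  signal <- study$signal
  acq <- study$acq
  stopifnot(length(dim(signal)) == 4L, inherits(acq, "dsc_acq"))
  nt <- dim(signal)[4]
  if (is.null(baseline_window)) baseline_window <- detect_baseline_window(study)
  baseline_window <- as.integer(baseline_window)
  if (length(baseline_window) == 0L || any(baseline_window < 1L) ||
      any(baseline_window > nt))
    stop("invalid `baseline_window`", call. = FALSE)

  nvox <- prod(dim(signal)[1:3])
  smat <- matrix(signal, nrow = nvox, ncol = nt)
  s0 <- rowMeans(smat[, baseline_window, drop = FALSE])
  check <- if (is.null(mask)) rep(TRUE, nvox) else as.vector(mask)
  bad <- which(check & s0 <= 0)
  if (length(bad) > 0)
    stop("non-positive baseline mean in voxel(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)

  ratio <- smat / s0
  nonpos <- !is.finite(ratio) | ratio <= 0
  ratio[nonpos] <- 1  # maps to C = 0
  conc <- -log(ratio) / acq$te
  structure(
    list(data = array(conc, dim = dim(signal)), t_axis = acq$t_axis,
         baseline_window = baseline_window, n_clipped = sum(nonpos & check),
         acq = acq),
    class = "dsc_conc"
  )
}

#' Auto-detect the pre-bolus baseline window
#'
#' Takes timepoints 1..8, or all points before the global-mean signal first
#' drops 5% below the running mean of the preceding points, whichever is
#' shorter.
#'
#' @param study A `dsc_study` (or list with 4D `signal`).
#' @param max_len Maximum window length.
#' @param drop_fraction Relative drop that marks bolus arrival.
#' @return Integer vector of baseline timepoint indices.
#' @export
detect_baseline_window <- function(study, max_len = 8L, drop_fraction = 0.05) {
  signal <- study$signal
  nt <- dim(signal)[4]
  gmean <- apply(matrix(signal, ncol = nt), 2, mean)
  arrival <- nt
  for (t in 2:nt) {
    if (gmean[t] < (1 - drop_fraction) * mean(gmean[1:(t - 1)])) {
      arrival <- t
      break
    }
  }
  seq_len(max(1L, min(max_len, arrival - 1L)))
}

#' Descriptors of a single concentration-time curve
#'
#' Computes the peak concentration (Cmax), time-to-peak (TTP, first index on
#' ties) and the first-moment transit time
#' \eqn{fMTT = \sum t C(t) / \sum C(t)} over the nonnegative-clipped curve.
#' A zero-mass curve yields fmtt = 0 with `zero_mass = TRUE`.
#'
#' @param curve Finite numeric concentration curve.
#' @param t_axis Time axis, seconds, same length as `curve`.
#' @return List with `cmax`, `ttp`, `fmtt`, `zero_mass`.
#' @export
curve_descriptors <- function(curve, t_axis) {
  if (length(curve) != length(t_axis))
    stop("`curve` and `t_axis` lengths differ", call. = FALSE)
  if (any(!is.finite(curve))) stop("`curve` must be finite", call. = FALSE)
  pos <- pmax(curve, 0)
  pk <- which.max(pos)
  mass <- sum(pos)
  list(
    cmax = pos[pk],
    ttp = t_axis[pk],
    fmtt = if (mass > 0) sum(t_axis * pos) / mass else 0,
    zero_mass = mass <= 0
  )
}

#' Voxelwise descriptor maps (Cmax, TTP, fMTT)
#'
#' Vectorized [curve_descriptors()] over a concentration volume. Voxels
#' outside `mask` are 0.
#'
#' @param conc A `dsc_conc` object.
#' @param mask Optional 3D logical array restricting computation.
#' @return List of 3D arrays `cmax`, `ttp`, `fmtt` and logical `zero_mass`.
#' @export
descriptor_maps <- function(conc, mask = NULL) {
  dims <- dim(conc$data)
  nvox <- prod(dims[1:3]); nt <- dims[4]
  cmat <- matrix(conc$data, nrow = nvox, ncol = nt)
  sel <- if (is.null(mask)) rep(TRUE, nvox) else as.vector(mask)
  cmat <- pmax(cmat[sel, , drop = FALSE], 0)
  # first-index argmax per row
  pk <- max.col(cmat, ties.method = "first")
  cmax <- cmat[cbind(seq_len(nrow(cmat)), pk)]
  mass <- rowSums(cmat)
  fmtt <- as.vector(cmat %*% conc$t_axis)
  fmtt <- ifelse(mass > 0, fmtt / mass, 0)

  out <- lapply(c("cmax", "ttp", "fmtt"), function(nm) array(0, dims[1:3]))
  names(out) <- c("cmax", "ttp", "fmtt")
  out$cmax[sel] <- cmax
  out$ttp[sel] <- conc$t_axis[pk]
  out$fmtt[sel] <- fmtt
  out$zero_mass <- array(FALSE, dims[1:3])
  out$zero_mass[sel] <- mass <= 0
  out
}
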