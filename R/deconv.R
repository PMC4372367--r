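#' Truncated-SVD deconvolution of a tissue curve
#'
#' Builds the lower-triangular Toeplitz convolution matrix
#' `A[i, j] = dt * aif[i - j + 1]` (j <= i), forms the pseudo-inverse with
#' singular values below `svd_threshold * sigma_max` zeroed, and applies it
#' to the tissue curve. The flow-scaled residue is `A^+ tissue`; its maximum
#' is the raw CBF estimate (read-out at the peak, not at t = 0, to tolerate
#' bolus delay).
#'
#' @param tissue_curve Tissue concentration curve.
#' @param aif A `dsc_aif` or a numeric AIF curve of the same length.
#' @param dt Sampling interval, seconds.
#' @param svd_threshold Fraction of the largest singular value below which
#'   singular values are zeroed (0 < threshold < 1); default 0.2, the
#'   classical standard-SVD choice.
#' @return List with `cbf_raw` (peak of the flow-scaled residue, arbitrary
#'   flow units) and `residue_curve` (residue normalized to peak 1 when
#'   `cbf_raw > 0`, otherwise the unscaled output).
#' @export
svd_deconvolve <- function(tissue_curve, aif, dt, svd_threshold = 0.2) {
  aif_curve <- if (inherits(aif, "dsc_aif")) aif$curve else aif
  if (length(tissue_curve) != length(aif_curve))
    stop("tissue and AIF curves must have equal length", call. = FALSE)
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  if (!(svd_threshold > 0 && svd_threshold < 1))
    stop("`svd_threshold` must be in (0, 1)", call. = FALSE)
  if (any(!is.finite(tissue_curve)) || any(!is.finite(aif_curve)))
    stop("NaN/Inf in input curves", call. = FALSE)
  if (sum(aif_curve) <= 0) stop("AIF has no positive mass", call. = FALSE)
  Ainv <- svd_pseudoinverse(aif_curve, dt, svd_threshold)
  residue_scaled <- as.vector(Ainv %*% tissue_curve)
  cbf_raw <- max(residue_scaled)
  list(
    cbf_raw = cbf_raw,
    residue_curve = if (cbf_raw > 0) residue_scaled / cbf_raw else residue_scaled
  )
}

# Toeplitz convolution matrix and its truncated-SVD pseudo-inverse
convolution_matrix <- function(aif_curve, dt) {
  n <- length(aif_curve)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) A[i, 1:i] <- dt * aif_curve[i:1]
  A
}

svd_pseudoinverse <- function(aif_curve, dt, svd_threshold) {
  A <- convolution_matrix(aif_curve, dt)
  s <- svd(A)
  keep <- s$d >= svd_threshold * max(s$d)
  dinv <- ifelse(keep, 1 / s$d, 0)
  s$v %*% (dinv * t(s$u))
}

#' Cerebral blood volume by the indicator-dilution integral ratio
#'
#' `cbv_raw = integral(tissue) / integral(AIF)` with trapezoidal quadrature;
#' negative samples are clipped to 0 before integrating. For calibrated
#' inputs the result is CBV/100 (dimensionless blood volume fraction).
#'
#' @param tissue_curve Tissue concentration curve.
#' @param aif_curve Arterial concentration curve (positive integral).
#' @param dt Sampling interval, seconds.
#' @return Scalar raw CBV (ratio of curve areas).
#' @export
compute_cbv <- function(tissue_curve, aif_curve, dt) {
  if (inherits(aif_curve, "dsc_aif")) aif_curve <- aif_curve$curve
  a <- trapz_area(pmax(aif_curve, 0), dt)
  if (a <= 0) stop("AIF has zero mass", call. = FALSE)
  trapz_area(pmax(tissue_curve, 0), dt) / a
}

trapz_area <- function(y, dt) {
  n <- length(y)
  (sum(y) - 0.5 * (y[1] + y[n])) * dt
}

#' Voxelwise CBF/CBV perfusion maps
#'
#' Applies [svd_deconvolve()] and [compute_cbv()] to every in-mask voxel of
#' a concentration volume (vectorized through a single precomputed
#' pseudo-inverse). Negative outputs are clipped to 0; out-of-mask voxels
#' are 0. Maps are in arbitrary units until calibrated by
#' [calibrate_maps()].
#'
#' @param conc A `dsc_conc` object.
#' @param aif A `dsc_aif` (or numeric AIF curve).
#' @param mask 3D logical array of voxels to process (nonempty).
#' @param svd_threshold SVD truncation fraction.
#' @return Object of class `dsc_maps`: 3D `cbf` and `cbv` arrays,
#'   `calibrated = FALSE`, `svd_threshold`, `aif`.
#' @export
make_maps <- function(conc, aif, mask, svd_threshold = 0.2) {
  aif_curve <- if (inherits(aif, "dsc_aif")) aif$curve else aif
  dims <- dim(conc$data)
  if (!all(dim(mask) == dims[1:3]))
    stop("mask shape does not match the volume", call. = FALSE)
  idx <- which(as.vector(mask))
  if (length(idx) == 0L) stop("mask is empty", call. = FALSE)
  dt <- conc$t_axis[2] - conc$t_axis[1]
  nt <- dims[4]
  cmat <- matrix(conc$data, nrow = prod(dims[1:3]), ncol = nt)[idx, , drop = FALSE]

  Ainv <- svd_pseudoinverse(aif_curve, dt, svd_threshold)
  res <- Ainv %*% t(cmat)                       # nt x nvox flow-scaled residues
  cbf <- do.call(pmax, lapply(seq_len(nt), function(i) res[i, ]))

  w <- rep(dt, nt); w[c(1, nt)] <- dt / 2       # trapezoid weights
  aif_area <- sum(pmax(aif_curve, 0) * w)
  if (aif_area <= 0) stop("AIF has zero mass", call. = FALSE)
  cbv <- as.vector(pmax(cmat, 0) %*% w) / aif_area

  out <- list(cbf = array(0, dims[1:3]), cbv = array(0, dims[1:3]),
              calibrated = FALSE, svd_threshold = svd_threshold,
              cal_factors = NULL, aif = aif)
  out$cbf[idx] <- pmax(cbf, 0)
  out$cbv[idx] <- pmax(cbv, 0)
  structure(out, class = "dsc_maps")
}
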