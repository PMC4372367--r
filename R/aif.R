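#' Rank voxels by arterial character
#'
#' Arterial concentration curves have high Cmax, short TTP and short fMTT.
#' Each in-mask voxel gets the composite score
#' `rank(-cmax) + rank(ttp) + rank(fmtt)` (ascending mid-ranks); lower is
#' more arterial. Output is sorted ascending by score, ties broken by higher
#' Cmax then lexicographic voxel index, so the ordering is independent of
#' voxel storage order.
#'
#' @param desc Descriptor maps from [descriptor_maps()].
#' @param search_mask 3D logical array of candidate voxels (nonempty).
#' @return A data.frame ordered most-arterial-first with columns `i`, `j`,
#'   `k`, `index` (linear), `cmax`, `ttp`, `fmtt`, `score`.
#' @export
rank_aif_candidates <- function(desc, search_mask) {
  idx <- which(as.vector(search_mask))
  if (length(idx) == 0L) stop("`search_mask` is empty", call. = FALSE)
  cmax <- desc$cmax[idx]; ttp <- desc$ttp[idx]; fmtt <- desc$fmtt[idx]
  score <- rank(-cmax, ties.method = "average") +
    rank(ttp, ties.method = "average") +
    rank(fmtt, ties.method = "average")
  ord <- order(score, -cmax, idx)
  co <- arrayInd(idx[ord], dim(desc$cmax))
  data.frame(i = co[, 1], j = co[, 2], k = co[, 3], index = idx[ord],
             cmax = cmax[ord], ttp = ttp[ord], fmtt = fmtt[ord],
             score = score[ord])
}

#' Build the arterial input function from ranked candidate voxels
#'
#' Averages the concentration curves of the best `n` candidates, smooths
#' with a centered moving average of odd width `smooth_window`, clips
#' negatives, and (optionally) truncates the curve — zeroes it after the
#' first local minimum following the global peak — to remove the second
#' (recirculation) pass of the tracer.
#'
#' @param conc A `dsc_conc` object.
#' @param candidates Ranked candidates from [rank_aif_candidates()].
#' @param n Number of voxels to average (default 20). If fewer candidates
#'   exist, all are used with a warning.
#' @param smooth_window Odd moving-average width; 1 disables smoothing.
#' @param truncate Remove the recirculation pass (default `TRUE`).
#' @return Object of class `dsc_aif`: `curve`, `t_axis`, `voxel_indices`
#'   (matrix of i, j, k), `n_selected`, `truncation_index` (last retained
#'   timepoint).
#' @export
build_aif <- function(conc, candidates, n = 20L, smooth_window = 3L,
                      truncate = TRUE) {
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  smooth_window <- as.integer(smooth_window)
  if (smooth_window < 1L || smooth_window %% 2L == 0L)
    stop("`smooth_window` must be a positive odd integer", call. = FALSE)
  if (nrow(candidates) < n) {
    warning(sprintf("only %d AIF candidates available (requested %d); using all",
                    nrow(candidates), n))
    n <- nrow(candidates)
  }
  top <- candidates[seq_len(n), ]
  dims <- dim(conc$data)
  nt <- dims[4]
  cmat <- matrix(conc$data, nrow = prod(dims[1:3]), ncol = nt)
  curve <- colMeans(cmat[top$index, , drop = FALSE])
  curve <- moving_average(curve, smooth_window)
  curve <- pmax(curve, 0)

  trunc_idx <- nt
  if (truncate) {
    pk <- which.max(curve)
    if (pk < nt - 1L) {
      for (j in (pk + 1L):(nt - 1L)) {
        if (curve[j] <= curve[j - 1L] && curve[j] < curve[j + 1L]) {
          trunc_idx <- j
          break
        }
      }
    }
    if (trunc_idx < nt) curve[(trunc_idx + 1L):nt] <- 0
  }
  structure(
    list(curve = curve, t_axis = conc$t_axis,
         voxel_indices = as.matrix(top[, c("i", "j", "k")]),
         n_selected = n, truncation_index = trunc_idx),
    class = "dsc_aif"
  )
}

# centered moving average with shrinking windows at the edges
moving_average <- function(x, width) {
  if (width <= 1L) return(x)
  half <- (width - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}
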