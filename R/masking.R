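#' Parenchyma mask from an anatomical volume
#'
#' Two-stage intensity segmentation: (1) a 2-class split separating
#' background from head, computed by maximizing between-class variance
#' (Otsu's criterion) on the intensity ranks so the split is invariant under
#' any strictly monotone intensity rescaling; (2) a 3-class quantile split of
#' head voxels keeping the upper two classes (voxels at or above the 1/3
#' empirical quantile, type-1 so the threshold is an order statistic).
#' Finally only the largest 6-connected component is retained.
#'
#' @param anatomical Finite, nonconstant 3D intensity array.
#' @return Object of class `dsc_mask` with `kind = "parenchyma"`.
#' @export
parenchyma_mask <- function(anatomical) {
  v <- as.vector(anatomical)
  if (any(!is.finite(v))) stop("anatomical volume must be finite", call. = FALSE)
  if (max(v) == min(v)) stop("anatomical volume is constant", call. = FALSE)
  r <- rank(v, ties.method = "average")
  thr <- otsu_threshold(r)
  head_sel <- r > thr
  head_vals <- v[head_sel]
  q <- stats::quantile(head_vals, 1 / 3, type = 1, names = FALSE)
  keep <- head_sel & v >= q
  m <- array(keep, dim = dim(anatomical))
  m <- largest_component(m)
  new_mask(m, "parenchyma",
           list(rank_threshold = thr, tissue_quantile = q))
}

# Otsu's between-class-variance threshold over the unique values of x;
# returns the threshold t such that the foreground is x > t.
otsu_threshold <- function(x) {
  u <- sort(unique(x))
  if (length(u) < 2L) return(u[1])
  n <- length(x)
  tab <- table(factor(x, levels = u))
  p <- as.vector(tab) / n
  omega <- cumsum(p)
  mu <- cumsum(p * u)
  mu_t <- mu[length(mu)]
  # between-class variance for threshold after each unique value (last excluded)
  k <- seq_len(length(u) - 1L)
  sigma_b <- (mu_t * omega[k] - mu[k])^2 / (omega[k] * (1 - omega[k]))
  u[k[which.max(sigma_b)]]
}

# largest 6-connected component of a 3D logical array (iterative BFS)
largest_component <- function(mask) {
  dims <- dim(mask)
  labels <- array(0L, dims)
  nxt <- 0L
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  todo <- which(mask & labels == 0L)
  while (length(todo) > 0L) {
    nxt <- nxt + 1L
    frontier <- todo[1]
    labels[frontier] <- nxt
    while (length(frontier) > 0L) {
      co <- arrayInd(frontier, dims)
      nb <- do.call(rbind, lapply(seq_len(6), function(s) {
        sweep(co, 2, shifts[s, ], "+")
      }))
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb_idx <- unique(nb[ok, 1] + (nb[ok, 2] - 1L) * dims[1] +
                         (nb[ok, 3] - 1L) * dims[1] * dims[2])
      frontier <- nb_idx[mask[nb_idx] & labels[nb_idx] == 0L]
      labels[frontier] <- nxt
    }
    todo <- which(mask & labels == 0L)
  }
  if (nxt <= 1L) return(mask)
  counts <- tabulate(labels[labels > 0L], nbins = nxt)
  array(labels == which.max(counts), dims)
}

#' Vessel mask from a Cmax map
#'
#' The median Cmax is computed over parenchyma voxels only (the parenchyma
#' mask is applied before taking the histogram, treated as the empirical
#' distribution); voxels whose Cmax is strictly greater than
#' `factor * median` are flagged as vessel.
#'
#' @param cmax_map 3D Cmax array.
#' @param parenchyma Parenchyma `dsc_mask` (nonempty).
#' @param factor Multiplicative threshold; default 3.0.
#' @return Object of class `dsc_mask` with `kind = "vessel"`.
#' @export
vessel_mask <- function(cmax_map, parenchyma, factor = 3.0) {
  p <- mask_data(parenchyma)
  if (!any(p)) stop("parenchyma mask is empty", call. = FALSE)
  if (factor <= 0) stop("`factor` must be > 0", call. = FALSE)
  m <- stats::median(cmax_map[p])
  if (m <= 0)
    stop("median parenchymal Cmax is not positive; vessel rule degenerates",
         call. = FALSE)
  new_mask(array(cmax_map > factor * m, dim = dim(cmax_map)), "vessel",
           list(factor = factor, median_cmax = m))
}

#' Analysis inclusion mask
#'
#' All voxels within the parenchyma mask but not in the vessel mask.
#'
#' @param parenchyma,vessel `dsc_mask` objects (or logical arrays) of equal
#'   shape.
#' @return Object of class `dsc_mask` with `kind = "inclusion"`. A warning
#'   is raised if the result is empty (fatal for downstream VOI statistics).
#' @export
inclusion_mask <- function(parenchyma, vessel) {
  p <- mask_data(parenchyma); v <- mask_data(vessel)
  if (!all(dim(p) == dim(v))) stop("mask shapes differ", call. = FALSE)
  inc <- p & !v
  if (!any(inc))
    warning("inclusion mask is empty; downstream VOI statistics will fail")
  new_mask(inc, "inclusion", list(n_included = sum(inc)))
}

new_mask <- function(data, kind, provenance = list()) {
  structure(list(data = data, kind = kind, provenance = provenance),
            class = "dsc_mask")
}

mask_data <- function(x) {
  if (inherits(x, "dsc_mask")) x$data else x
}
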