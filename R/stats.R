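#' Mann-Whitney U test (exact or asymptotic)
#'
#' The U statistic counts pairs with `x_i > y_j` plus half the tied pairs,
#' reported as `min(U, nm - U)`. In exact mode the two-sided p-value is the
#' null probability of a U at least as far from nm/2 as observed, by full
#' enumeration of all `choose(n + m, n)` group labelings of the pooled
#' sample; in asymptotic mode the normal approximation with tie-corrected
#' variance and continuity correction is used. Mode `"auto"` picks exact
#' when `n + m <= 12`.
#'
#' @param x,y Nonempty numeric samples.
#' @param mode `"auto"`, `"exact"` or `"asymptotic"`.
#' @return List with `statistic` (min-U), `p_value`, `mode` (the mode
#'   actually used).
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be nonempty", call. = FALSE)
  n <- length(x); m <- length(y)
  used <- if (mode == "auto") {
    if (n + m <= 12L) "exact" else "asymptotic"
  } else mode
  u <- u_statistic(x, y)
  u_min <- min(u, n * m - u)

  if (used == "exact") {
    pooled <- c(x, y)
    combs <- utils::combn(n + m, n)
    dev_obs <- abs(u - n * m / 2)
    hits <- 0L
    for (ci in seq_len(ncol(combs))) {
      sel <- combs[, ci]
      ui <- u_statistic(pooled[sel], pooled[-sel])
      if (abs(ui - n * m / 2) >= dev_obs - 1e-9) hits <- hits + 1L
    }
    p <- hits / ncol(combs)
  } else {
    N <- n + m
    ties <- table(c(x, y))
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n * m / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u - n * m / 2) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
  }
  list(statistic = u_min, p_value = p, mode = used)
}

u_statistic <- function(x, y) {
  cmp <- outer(x, y, ">") + 0.5 * outer(x, y, "==")
  sum(cmp)
}

#' Wilcoxon signed-rank test (exact or asymptotic)
#'
#' Computes signed ranks of the nonzero paired differences `left - right`
#' (zeros dropped and counted); W is `min(W+, W-)`. Exact mode enumerates
#' all `2^k` sign assignments (used when `k <= 12` in auto mode); otherwise
#' the normal approximation with continuity correction. If all differences
#' are zero the test is undefined and `status = "undefined"` is returned
#' (p is NA, not 1).
#'
#' @param left,right Paired samples of equal length >= 1.
#' @param mode `"auto"`, `"exact"` or `"asymptotic"`.
#' @return List with `statistic` (min of signed-rank sums), `p_value`,
#'   `n_zero` (dropped zero differences), `mode`, `status`.
#' @export
wilcoxon_signed_rank <- function(left, right,
                                 mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  if (length(left) != length(right) || length(left) < 1L)
    stop("`left` and `right` must be paired samples of equal length >= 1",
         call. = FALSE)
  d <- left - right
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  k <- length(d)
  if (k == 0L)
    return(list(statistic = NA_real_, p_value = NA_real_, n_zero = n_zero,
                mode = mode, status = "undefined"))
  r <- rank(abs(d), ties.method = "average")
  w_pos <- sum(r[d > 0])
  total <- sum(r)
  w <- min(w_pos, total - w_pos)
  used <- if (mode == "auto") {
    if (k <= 12L) "exact" else "asymptotic"
  } else mode

  if (used == "exact") {
    dev_obs <- abs(w_pos - total / 2)
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), k)))
    wp <- as.vector(signs %*% r)
    p <- mean(abs(wp - total / 2) >= dev_obs - 1e-9)
  } else {
    mu <- total / 2
    ties <- table(abs(d))
    sigma2 <- k * (k + 1) * (2 * k + 1) / 24 - sum(ties^3 - ties) / 48
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(w_pos - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
  }
  list(statistic = w, p_value = p, n_zero = n_zero, mode = used,
       status = "ok")
}

#' Median and interquartile range
#'
#' Linear-interpolation quantiles (positions `p*(n-1) + 1`, R type 7).
#'
#' @param values Nonempty numeric vector.
#' @return List with `median`, `q1`, `q3`.
#' @export
median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no non-missing values", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3])
}

#' Structure ordering used in comparison tables
#' @export
STRUCTURE_ORDER <- c("amygdala", "hippocampus", "thalamus", "putamen",
                     "globus_pallidus", "caudate")

#' Group and laterality comparison of VOI measurements
#'
#' For every structure x side x metric (rCBF, rCBV), compares patients
#' against controls with the Mann-Whitney U test; additionally, for every
#' structure x metric, compares right vs left within patients with the
#' Wilcoxon signed-rank test. Medians and IQRs are reported per group.
#' P-values are unadjusted (no multiplicity correction is applied; the
#' `n_tests` attribute carries the row count for users who want to apply
#' their own). Rows follow the order amygdala, hippocampus, thalamus,
#' putamen, globus pallidus, caudate; right before left.
#'
#' @param measurements Data.frame of VOI rows from [extract_voi_values()]
#'   (stacked over subjects), with a `group` column of `"patient"` /
#'   `"control"`.
#' @param alpha Significance level (default 0.05).
#' @param mode Test mode passed to the tests (`"auto"`, `"exact"`,
#'   `"asymptotic"`).
#' @return Data.frame of class `dsc_comparison`: one row per contrast with
#'   `structure`, `side`, `contrast` (`"group"` or `"laterality"`),
#'   `metric`, medians/IQRs, `statistic`, `p_value`, `mode`, `significant`.
#' @export
run_group_analysis <- function(measurements, alpha = 0.05,
                               mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  stopifnot(all(c("group", "structure", "side") %in% names(measurements)))
  metrics <- c("rcbf", "rcbv")
  rows <- list()

  for (s in STRUCTURE_ORDER) {
    for (sd in c("right", "left")) {
      for (met in metrics) {
        sub <- measurements[measurements$structure == s &
                              measurements$side == sd, ]
        pa <- sub[[met]][sub$group == "patient"]
        co <- sub[[met]][sub$group == "control"]
        pa <- pa[!is.na(pa)]; co <- co[!is.na(co)]
        if (length(pa) == 0L || length(co) == 0L) {
          rows[[length(rows) + 1L]] <- comparison_row(
            s, sd, "group", met, pa, co, NA_real_, NA_real_, "missing", alpha)
          next
        }
        tst <- mann_whitney_u(pa, co, mode)
        rows[[length(rows) + 1L]] <- comparison_row(
          s, sd, "group", met, pa, co, tst$statistic, tst$p_value, tst$mode,
          alpha)
      }
    }
  }
  # within-patient laterality: paired right vs left
  pat <- measurements[measurements$group == "patient", ]
  for (s in STRUCTURE_ORDER) {
    for (met in metrics) {
      r_sub <- pat[pat$structure == s & pat$side == "right", ]
      l_sub <- pat[pat$structure == s & pat$side == "left", ]
      ids <- intersect(r_sub$subject_id, l_sub$subject_id)
      rv <- r_sub[[met]][match(ids, r_sub$subject_id)]
      lv <- l_sub[[met]][match(ids, l_sub$subject_id)]
      keep <- !is.na(rv) & !is.na(lv)
      if (sum(keep) == 0L) {
        rows[[length(rows) + 1L]] <- comparison_row(
          s, "both", "laterality", met, numeric(0), numeric(0),
          NA_real_, NA_real_, "missing", alpha)
        next
      }
      tst <- wilcoxon_signed_rank(lv[keep], rv[keep], mode)
      rows[[length(rows) + 1L]] <- comparison_row(
        s, "both", "laterality", met, lv[keep], rv[keep],
        tst$statistic, tst$p_value,
        if (tst$status == "undefined") "undefined" else tst$mode, alpha)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_tests") <- sum(!is.na(out$p_value))
  attr(out, "alpha") <- alpha
  class(out) <- c("dsc_comparison", "data.frame")
  out
}

comparison_row <- function(structure, side, contrast, metric, g1, g2,
                           statistic, p, mode, alpha) {
  mi <- function(v) {
    if (length(v) == 0L) return(list(median = NA_real_, q1 = NA_real_,
                                     q3 = NA_real_))
    median_iqr(v)
  }
  a <- mi(g1); b <- mi(g2)
  data.frame(
    structure = structure, side = side, contrast = contrast, metric = metric,
    n_1 = length(g1), n_2 = length(g2),
    median_1 = a$median, q1_1 = a$q1, q3_1 = a$q3,
    median_2 = b$median, q1_2 = b$q1, q3_2 = b$q3,
    statistic = statistic, p_value = p, mode = mode,
    significant = !is.na(p) & p < alpha,
    stringsAsFactors = FALSE
  )
}

#' Format a comparison table as markdown text
#'
#' Renders group-contrast rows of a [run_group_analysis()] result as a
#' "median (IQR)" table, one metric at a time.
#'
#' @param results A `dsc_comparison` data.frame.
#' @param metric `"rcbf"` or `"rcbv"`.
#' @return Character vector of table lines.
#' @export
format_comparison_table <- function(results, metric = c("rcbf", "rcbv")) {
  metric <- match.arg(metric)
  sub <- results[results$contrast == "group" & results$metric == metric, ]
  fmt <- function(m, q1, q3) sprintf("%.2f (%.2f-%.2f)", m, q1, q3)
  lines <- c(
    sprintf("| Region | Patients %s | Controls %s | p |", metric, metric),
    "|---|---|---|---|"
  )
  for (i in seq_len(nrow(sub))) {
    r <- sub[i, ]
    lab <- paste(ifelse(r$side == "right", "R", "L"),
                 gsub("_", " ", r$structure))
    lines <- c(lines, sprintf(
      "| %s | %s | %s | %s |", lab,
      fmt(r$median_1, r$q1_1, r$q3_1), fmt(r$median_2, r$q1_2, r$q3_2),
      ifelse(is.na(r$p_value), "NA", sprintf("%.3f", r$p_value))))
  }
  lines
}
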