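test_that("Mann-Whitney U: symmetry, textbook case, error handling", {
  x <- c(1, 2, 3, 4)
  r <- mann_whitney_u(x, x, mode = "exact")
  expect_equal(r$statistic, length(x)^2 / 2)
  expect_equal(r$p_value, 1)

  # complete separation of 3 vs 3: U = 0, p = 2/20
  r2 <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), mode = "exact")
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 0.1)

  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("exact Mann-Whitney p equals wilcox.test on tie-free data", {
  set.seed(71)
  for (i in 1:50) {
    x <- stats::rnorm(5); y <- stats::rnorm(5, mean = stats::runif(1, -1, 1))
    r <- mann_whitney_u(x, y, mode = "exact")
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(r$p_value, ref$p.value, tolerance = 1e-12,
                 label = sprintf("dataset %d", i))
    # wilcox.test W is U(x over y); ours is the min-form
    expect_equal(r$statistic, min(ref$statistic, 25 - ref$statistic))
  }
})

test_that("auto mode switches at total n = 12 and asymptotic approximates exact", {
  set.seed(72)
  x <- stats::rnorm(6); y <- stats::rnorm(6)
  expect_equal(mann_whitney_u(x, y)$mode, "exact")
  expect_equal(mann_whitney_u(c(x, 1), y)$mode, "asymptotic")

  # tie-corrected normal approximation tracks wilcox.test's
  x2 <- stats::rnorm(8); y2 <- stats::rnorm(10, 0.5)
  r <- mann_whitney_u(x2, y2, mode = "asymptotic")
  ref <- stats::wilcox.test(x2, y2, exact = FALSE, correct = TRUE)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("Wilcoxon signed-rank: shift case, antisymmetry, zero handling", {
  l <- c(5, 6, 7, 8, 9)
  r <- wilcoxon_signed_rank(l + 2, l, mode = "exact")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 2 / 32)

  # antisymmetric differences: W+ = W-, p = 1
  left <- c(10, 10, 10, 10); right <- c(10 - 2, 10 + 2, 10 - 5, 10 + 5)
  r2 <- wilcoxon_signed_rank(left, right, mode = "exact")
  expect_equal(r2$p_value, 1)

  # zero differences are dropped and counted
  r3 <- wilcoxon_signed_rank(c(1, 2, 3, 4), c(1, 2, 2, 3), mode = "exact")
  expect_equal(r3$n_zero, 2L)

  # all-zero differences: undefined, not p = 1
  r4 <- wilcoxon_signed_rank(c(1, 2), c(1, 2))
  expect_equal(r4$status, "undefined")
  expect_true(is.na(r4$p_value))
})

test_that("exact Wilcoxon p equals wilcox.test sign-flip enumeration", {
  set.seed(73)
  for (i in 1:50) {
    l <- stats::rnorm(6); r <- l + stats::rnorm(6, sd = 1.5)
    ours <- wilcoxon_signed_rank(l, r, mode = "exact")
    ref <- stats::wilcox.test(l, r, paired = TRUE, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12,
                 label = sprintf("dataset %d", i))
  }
})

test_that("median and IQR use linear-interpolation quantiles", {
  m <- median_iqr(c(1, 2, 3, 4, 5))
  expect_equal(c(m$median, m$q1, m$q3), c(3, 2, 4))
  m2 <- median_iqr(rep(7, 10))
  expect_equal(c(m2$median, m2$q1, m2$q3), c(7, 7, 7))
  set.seed(74)
  v <- stats::rnorm(100)
  m3 <- median_iqr(v)
  sv <- sort(v)
  qpos <- function(p) {
    h <- p * 99 + 1
    sv[floor(h)] + (h - floor(h)) * (sv[floor(h) + 1] - sv[floor(h)])
  }
  expect_equal(m3$q1, qpos(0.25))
  expect_equal(m3$q3, qpos(0.75))
  expect_error(median_iqr(NA_real_), "non-missing")
})

make_voi_frame <- function(values_by_group) {
  # build a measurement frame for one structure, both sides, metric rcbf
  rows <- list()
  for (g in names(values_by_group)) {
    vals <- values_by_group[[g]]
    for (i in seq_along(vals)) {
      for (sd in c("right", "left")) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = paste0(g, i), group = g, structure = "hippocampus",
          side = sd, n_voxels = 9L, cbf_mean = 1, cbv_mean = 1,
          rcbf = vals[i] + ifelse(sd == "left", 0.001 * i, 0),
          rcbv = vals[i], stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

test_that("group analysis rows match a direct test on the same values", {
  pa <- c(1.2, 1.1, 1.3, 1.0, 1.15)
  co <- c(1.4, 1.5, 1.35, 1.45, 1.6, 1.3, 1.55, 1.42, 1.38, 1.47,
          1.52, 1.33, 1.41, 1.58, 1.36)
  voi <- make_voi_frame(list(patient = pa, control = co))
  res <- run_group_analysis(voi)
  row <- res[res$structure == "hippocampus" & res$side == "right" &
               res$contrast == "group" & res$metric == "rcbf", ]
  ref <- mann_whitney_u(pa, co, mode = "auto")
  expect_equal(row$p_value, ref$p_value)
  expect_equal(row$statistic, ref$statistic)
  expect_equal(row$median_1, stats::median(pa))
  expect_equal(row$q1_2, unname(stats::quantile(co, 0.25)))
  # extreme separation is significant at the asymptotic minimum
  expect_true(row$significant)
})

test_that("analysis output is ordered right-before-left by structure and includes laterality rows", {
  st <- generate_study(small_acq(), noise_sigma = 10, seed = 75L)
  voi_p <- quantify_study(st, small_config(), subject_id = "P1",
                          group = "patient")$voi
  st2 <- generate_study(small_acq(), noise_sigma = 10, seed = 76L)
  voi_c <- quantify_study(st2, small_config(), subject_id = "C1",
                          group = "control")$voi
  res <- run_group_analysis(rbind(voi_p, voi_c))
  grp <- res[res$contrast == "group" & res$metric == "rcbf", ]
  expect_equal(grp$structure,
               rep(c("amygdala", "hippocampus", "thalamus", "putamen",
                     "globus_pallidus", "caudate"), each = 2))
  expect_equal(grp$side, rep(c("right", "left"), 6))
  lat <- res[res$contrast == "laterality", ]
  expect_equal(nrow(lat), 12L)  # 6 structures x 2 metrics
  # single patient: laterality test has k = 1 pair, still defined
  expect_true(all(lat$mode %in% c("exact", "undefined")))
  expect_false(any(is.na(res$p_value[res$contrast == "group"])))
})

test_that("no multiplicity adjustment is applied and alpha flags agree", {
  pa <- c(0.1, 0.2, 0.3, 0.15, 0.25)
  co <- seq(1, 2, length.out = 15)
  voi <- make_voi_frame(list(patient = pa, control = co))
  res <- run_group_analysis(voi, alpha = 0.05)
  grp <- res[res$contrast == "group" & res$metric == "rcbf" &
               res$structure == "hippocampus", ]
  expect_equal(grp$significant, grp$p_value < 0.05)
  expect_equal(attr(res, "alpha"), 0.05)
  expect_true(attr(res, "n_tests") >= nrow(grp))
})
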