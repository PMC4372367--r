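test_that("gamma-variate curve: zero amplitude, analytic peak, quadrature area", {
  t <- seq(0, 60, by = 0.5)

  expect_equal(gamma_variate_curve(t, 10, 3, 1.5, 0), rep(0, length(t)))

  # analytic argmax at t0 + alpha*beta, peak value = amplitude
  for (p in list(c(5, 2, 1.5), c(10, 3, 1.5), c(8, 1.2, 4))) {
    tf <- seq(0, 80, by = 0.001)
    y <- gamma_variate_curve(tf, p[1], p[2], p[3], 7)
    expect_equal(tf[which.max(y)], p[1] + p[2] * p[3], tolerance = 1e-3)
    expect_equal(max(y), 7, tolerance = 1e-6)
  }

  # area matches independent quadrature of the closed form at dt = 0.1 s
  tq <- seq(0, 120, by = 0.1)
  y <- gamma_variate_curve(tq, 10, 3, 1.5, 10)
  y_ref <- gamma_closed_form(tq, 10, 3, 1.5, 10)
  expect_equal(trapz_oracle(tq, y), trapz_oracle(tq, y_ref),
               tolerance = 1e-3)
  expect_true(all(is.finite(y)))
  expect_true(all(y[tq <= 10] == 0))
})

test_that("gamma-variate curve rejects bad shape parameters", {
  expect_error(gamma_variate_curve(0:10, 2, -1, 1.5, 1), "alpha")
  expect_error(gamma_variate_curve(0:10, 2, 3, 0, 1), "beta")
})

test_that("tissue synthesis: zero flow, delta limit, central volume theorem", {
  dt <- 0.05
  t <- seq(0, 90, by = dt)
  aif <- gamma_variate_curve(t, 10, 3, 1.5, 40)

  expect_equal(synthesize_tissue_curve(aif, 0, 4, dt), rep(0, length(t)))

  # boxcar residue collapsing to one bin returns a scaled copy of the AIF
  tis <- synthesize_tissue_curve(aif, 60, dt, dt, residue_model = "boxcar")
  expect_equal(tis, (60 / 6000) * dt * aif, tolerance = 1e-12)

  # CBV from the integral ratio recovers CBF*MTT/60 (exponential residue)
  tis <- synthesize_tissue_curve(aif, 60, 4, dt)
  cbv <- 100 * trapz_oracle(t, tis) / trapz_oracle(t, aif)
  expect_equal(cbv, 4.0, tolerance = 0.02 * 4)
})

test_that("tissue synthesis agrees with a direct convolution oracle", {
  dt <- 0.5
  t <- seq(0, 60, by = dt)
  aif <- gamma_variate_curve(t, 8, 3, 1.5, 40)
  for (model in c("exponential", "boxcar")) {
    tis <- synthesize_tissue_curve(aif, 45, 5, dt, residue_model = model)
    R <- if (model == "exponential") exp(-(t - t[1]) / 5) else as.numeric(t - t[1] < 5)
    direct <- vapply(seq_along(t), function(i) {
      sum(aif[1:i] * R[i:1])
    }, numeric(1))
    expect_equal(tis, (45 / 6000) * dt * direct, tolerance = 1e-10)
  }
})

test_that("generated studies invert exactly without noise and are deterministic", {
  acq <- small_acq()
  st <- generate_study(acq, noise_sigma = 0)

  # noise-free signal inverts to the generator's concentration
  conc <- signal_to_concentration(st, baseline_window = 1:6)
  wm <- which(st$label_map == PHANTOM_LABELS$white_matter)[1]
  co <- arrayInd(wm, dim(st$label_map))
  expect_equal(conc$data[co[1], co[2], co[3], ],
               st$conc_true[, as.character(PHANTOM_LABELS$white_matter)],
               tolerance = 1e-9)

  # identical seeds give identical volumes; different seeds differ
  s1 <- generate_study(acq, noise_sigma = 15, seed = 11L)
  s2 <- generate_study(acq, noise_sigma = 15, seed = 11L)
  s3 <- generate_study(acq, noise_sigma = 15, seed = 12L)
  expect_identical(s1$signal, s2$signal)
  expect_false(identical(s1$signal, s3$signal))

  expect_error(generate_study(acq, noise_sigma = -1), "noise_sigma")
})

test_that("regional CBV from generated curves matches ground truth within 3%", {
  acq <- small_acq()
  st <- generate_study(acq, noise_sigma = 0)
  truths <- st$truths
  aif_col <- as.character(PHANTOM_LABELS$artery)
  for (nm in c("white_matter", "hippocampus_r", "thalamus_l", "putamen_r")) {
    row <- truth_row(truths, nm)
    tis <- st$conc_true[, as.character(row$label_id)]
    cbv <- 100 * trapz_oracle(acq$t_axis, tis) /
      trapz_oracle(acq$t_axis, st$conc_true[, aif_col])
    expect_equal(cbv, row$cbv_true, tolerance = 0.03 * row$cbv_true,
                 label = nm)
  }
})

test_that("arterial voxels dominate Cmax in a noise-free study", {
  st <- generate_study(small_acq(), noise_sigma = 0)
  conc <- signal_to_concentration(st, baseline_window = 1:6)
  nvox <- prod(dim(st$label_map))
  cmat <- matrix(conc$data, nrow = nvox)
  cmax <- apply(cmat, 1, max)
  expect_true(st$label_map[which.max(cmax)] == PHANTOM_LABELS$artery)
  # every arterial voxel beats every non-arterial voxel
  art <- st$label_map == PHANTOM_LABELS$artery
  expect_gt(min(cmax[art]), max(cmax[!art]))
})

test_that("truth table satisfies central-volume consistency", {
  truths <- tissue_truth_table()
  expect_equal(truths$mtt_true, 60 * truths$cbv_true / truths$cbf_true)
  expect_true(all(truths$cbf_true >= 0))
  expect_true(all(truths$mtt_true[truths$cbf_true > 0] > 0))
})

test_that("cohort generation: sizes, null case, effect application", {
  acq <- small_acq()
  des <- cohort_design(n_patients = 5L, controls_per_patient = 3L,
                       effect_fraction = 0.8, seed = 3L)
  subj <- generate_cohort(des, acq, materialize = FALSE)
  expect_length(subj, 20L)
  expect_equal(sum(vapply(subj, `[[`, "", "group") == "patient"), 5L)
  expect_equal(sum(vapply(subj, `[[`, "", "group") == "control"), 15L)

  # patients have scaled truth in effect regions only, and MTT is preserved
  pt <- subj[[1]]$truths; ct <- subj[[6]]$truths
  hr <- truth_row(pt, "hippocampus_r")
  expect_equal(hr$cbf_true, 0.8 * truth_row(ct, "hippocampus_r")$cbf_true)
  expect_equal(hr$mtt_true, truth_row(ct, "hippocampus_r")$mtt_true)
  expect_equal(truth_row(pt, "thalamus_r")$cbf_true,
               truth_row(ct, "thalamus_r")$cbf_true)

  # null design: identical truth tables for both groups
  null_subj <- generate_cohort(cohort_design(effect_fraction = 1, seed = 3L),
                               acq, materialize = FALSE)
  expect_identical(null_subj[[1]]$truths, null_subj[[6]]$truths)

  expect_error(generate_cohort(cohort_design(effect_regions = "nonexistent"),
                               acq), "effect regions")
})

test_that("generated hippocampal concentration scales with the effect fraction", {
  # measured from generated curves: patient/control ratio of hippocampal
  # curve mass tracks effect_fraction (CBV scales linearly with it)
  acq <- small_acq()
  eff <- 0.75
  des <- cohort_design(n_patients = 2L, controls_per_patient = 1L,
                       effect_fraction = eff, noise_sigma = 0, seed = 5L)
  subj <- generate_cohort(des, acq)
  hip <- as.character(PHANTOM_LABELS$hippocampus_r)
  mass <- vapply(subj, function(s) sum(s$study$conc_true[, hip]), numeric(1))
  grp <- vapply(subj, `[[`, "", "group")
  expect_equal(mean(mass[grp == "patient"]) / mean(mass[grp == "control"]),
               eff, tolerance = 1e-6)
})
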