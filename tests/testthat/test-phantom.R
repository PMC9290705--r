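test_that("default protocol matches the mouse liver acquisition and rejects bad inputs", {
  p <- acquisition_protocol()
  expect_equal(p$t1_map_tr, 15)
  expect_equal(p$t1_map_flip_angles, c(5, 26))
  expect_equal(p$t2_map_tes, c(17.4, 34.8, 52.2, 69.6, 87.0, 104.4))
  expect_equal(p$t2star_map_tes, c(6.71, 17.89, 29.07, 40.25, 51.43))
  expect_equal(p$dwi_b_values, c(0, 50, 100, 150, 200, 400, 600, 800, 1000))

  expect_error(acquisition_protocol(t1_map_flip_angles = 5), "two flip angles")
  expect_error(acquisition_protocol(t1_map_flip_angles = c(5, 95)), "\\(0, 90\\]")
  expect_error(acquisition_protocol(t2_map_tes = c(30, 20, 10)), "increasing")
  expect_error(acquisition_protocol(dwi_b_values = c(50, 100)), "start at 0")
})

test_that("tissue parameter invariants are enforced", {
  expect_error(tissue_params(900, 950, 35, 12, 1.2, 1.0), "delta_t1")
  expect_error(tissue_params(900, 400, 35, 12, 1.2, 1.0, f = 1.2), "f must lie")
  expect_error(tissue_params(900, 400, 35, 12, 1.2, 1.0, d_star = 0.5),
               "d_star > d")
  expect_error(tissue_params(-1, -2, 35, 12, 1.2, 1.0), "positive")
})

test_that("default design yields 54 animals and 102 lobe records", {
  co <- sample_cohort(cohort_design(seed = 1))
  expect_equal(length(unique(co$animal_id)), 54)
  expect_equal(nrow(co), 102)
  expect_equal(sum(co$lobe == "ligated"), 48)
  expect_equal(sum(co$lobe == "non_ligated"), 48)
  expect_equal(sum(co$lobe == "sham"), 6)
  # two lobes per PBDL animal share one id
  pbdl <- co[co$group == "pbdl", ]
  expect_true(all(table(pbdl$animal_id) == 2))
  # physical invariants hold for every sampled lobe
  expect_true(all(co$t1_native > 0 & co$t2 > 0 & co$t2star > 0))
  expect_true(all(co$delta_t1 < co$t1_native))
  expect_true(all(co$f >= 0 & co$f <= 1))
  expect_true(all(co$d_star > co$d & co$d > 0))
})

test_that("zero-sd design returns every cell mean exactly", {
  tab <- pbdl_parameter_table()
  tab$sd <- 0
  co <- sample_cohort(cohort_design(parameter_table = tab, seed = 5))
  lig2 <- co[co$lobe == "ligated" & co$timepoint_weeks == 2, ][1, ]
  expect_equal(lig2$t1_native, 966.31)
  expect_equal(lig2$delta_t1, 468.083)
  expect_equal(lig2$t2, 35.922)
  expect_equal(lig2$adc, 1.179)
  sham <- co[co$lobe == "sham", ][1, ]
  expect_equal(sham$t1_native, 901.000)
  expect_equal(sham$adc, 1.363)
})

test_that("a missing calibration cell is reported by name", {
  tab <- pbdl_parameter_table()
  tab <- tab[!(tab$group == "ligated" & tab$parameter == "t2" &
                 tab$timepoint_weeks %in% 4), ]
  expect_error(sample_cohort(cohort_design(parameter_table = tab, seed = 1)),
               "ligated, 4, t2")
})

test_that("same seed gives a bit-identical cohort, different seed does not", {
  a <- sample_cohort(cohort_design(seed = 123))
  b <- sample_cohort(cohort_design(seed = 123))
  c <- sample_cohort(cohort_design(seed = 124))
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("cohort sample means converge to the calibration cell means", {
  # 10,000 ligated 2-week lobes; each field's mean within 3 sd / sqrt(N)
  d <- cohort_design(timepoints = 2, n_pbdl_per_timepoint = 10000,
                     n_sham = 0, seed = 77)
  co <- sample_cohort(d)
  lig <- co[co$lobe == "ligated", ]
  tab <- pbdl_parameter_table()
  for (p in c("t1_native", "delta_t1", "t2", "t2star", "adc", "d")) {
    cell <- tab[tab$group == "ligated" & tab$timepoint_weeks == 2 &
                  tab$parameter == p, ]
    tol <- 3 * cell$sd / sqrt(nrow(lig))
    expect_lt(abs(mean(lig[[p]]) - cell$mean), tol + 1e-12)
  }
})

test_that("histology staging follows the PBDL trajectory", {
  expect_equal(assign_histology("ligated", 8),
               list(fibrosis_stage = 3L, activity_stage = 3L))
  expect_equal(assign_histology("ligated", 2),
               list(fibrosis_stage = 1L, activity_stage = 2L))
  expect_equal(assign_histology("ligated", 4),
               list(fibrosis_stage = 2L, activity_stage = 3L))
  expect_equal(assign_histology("ligated", 6),
               list(fibrosis_stage = 2L, activity_stage = 2L))
  for (tp in c(2, 4, 6, 8)) {
    expect_equal(assign_histology("sham", tp),
                 list(fibrosis_stage = 0L, activity_stage = 0L))
    expect_equal(assign_histology("non_ligated", tp),
                 list(fibrosis_stage = 0L, activity_stage = 0L))
  }
  expect_error(assign_histology("liver", 2), "unknown group")
  expect_error(assign_histology("ligated", 3), "unknown timepoint")
})

test_that("jittered histology stays in range and pins the 8-week endpoint", {
  set.seed(9)
  for (i in 1:200) {
    tp <- sample(c(2, 4, 6, 8), 1)
    h <- assign_histology("ligated", tp, mode = "jittered", jitter_prob = 0.5)
    expect_true(h$fibrosis_stage %in% 0:4)
    expect_true(h$activity_stage %in% 0:3)
    if (tp == 8) {
      expect_equal(h$fibrosis_stage, 3L)
      expect_equal(h$activity_stage, 3L)
    }
  }
})

test_that("forward signal models match their closed forms", {
  # two-b-value diffusion oracle: S(800) = 1000 * exp(-0.8 * 1.179)
  expect_equal(dwi_signal_monoexp(1000, 1.179, 800),
               1000 * exp(-0.8 * 1.179), tolerance = 1e-12)
  expect_equal(dwi_signal_monoexp(1000, 1.179, 800), 389.4, tolerance = 1e-3)
  # echo decay at TE = T2 is m0 / e
  expect_equal(echo_decay_signal(35.9, 1000, 35.9), 1000 / exp(1))
  # IVIM collapses to mono-exponential at f = 0
  b <- c(0, 50, 100, 150, 200, 400, 600, 800, 1000)
  expect_equal(dwi_signal_ivim(1000, 0, 1.1, 50, b),
               dwi_signal_monoexp(1000, 1.1, b))
})

test_that("noiseless signals are positive and monotone decreasing in b and TE", {
  tp <- tissue_params(966.31, 468.083, 35.922, 12.729, adc = 1.179, d = 1.087)
  v <- simulate_lobe_volumes(tp, acquisition_protocol(),
                             grid_shape = c(4, 4, 1), sigma = 0)
  roi_vox <- which(v$roi_mask)[1]
  for (series in list(v$t2_echoes, v$t2star_echoes, v$dwi)) {
    m <- series_matrix(series)[roi_vox, ]
    expect_true(all(m > 0))
    expect_true(all(diff(m) < 0))
  }
})

test_that("Rician noise has the right limiting means and determinism", {
  set.seed(31)
  # at signal 0 the mean is sigma * sqrt(pi / 2)
  x0 <- add_rician_noise(rep(0, 2e5), 10)
  expect_equal(mean(x0), 10 * sqrt(pi / 2), tolerance = 0.01)
  # at high SNR the mean converges to the signal
  xs <- add_rician_noise(rep(1000, 2e5), 10)
  expect_equal(mean(xs), 1000, tolerance = 1e-3)
  # intermediate signal matches the closed-form Rician mean
  xm <- add_rician_noise(rep(25, 2e5), 10)
  expect_equal(mean(xm), oracle_rician_mean(25, 10), tolerance = 0.01)
  expect_error(add_rician_noise(1, -1), "nonnegative")
  # same seed, same volumes
  tp <- tissue_params(900, 400, 35, 13, adc = 1.2, d = 1.0)
  v1 <- simulate_lobe_volumes(tp, acquisition_protocol(),
                              grid_shape = c(4, 4, 1), snr = 50, seed = 7)
  v2 <- simulate_lobe_volumes(tp, acquisition_protocol(),
                              grid_shape = c(4, 4, 1), snr = 50, seed = 7)
  expect_identical(v1$dwi, v2$dwi)
})

test_that("masks are disjoint and exclusion voxels are out of distribution", {
  tp <- tissue_params(900, 400, 35, 13, adc = 1.2, d = 1.0)
  v <- simulate_lobe_volumes(tp, acquisition_protocol(),
                             grid_shape = c(8, 8, 2), sigma = 0)
  expect_false(any(v$roi_mask & v$exclusion_mask))
  expect_true(all(v$dwi >= 0))
  s <- series_matrix(v$dwi)
  roi_level <- mean(s[which(v$roi_mask), 1])
  excl_level <- mean(s[which(v$exclusion_mask), 1])
  expect_gt(excl_level, 2 * roi_level)
})
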