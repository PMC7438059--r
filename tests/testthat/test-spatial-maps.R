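test_that("map distance is a normalized metric with the documented values", {
  z4 <- map_from_values(c(0, 0, 0, 0), 2, 2)
  o4 <- map_from_values(c(1, 1, 1, 1), 2, 2)
  e4 <- map_from_values(c(1, 0, 0, 0), 2, 2)
  expect_equal(map_distance(z4, z4), 0)
  expect_equal(map_distance(z4, o4), 1)
  expect_equal(map_distance(z4, e4), 0.5)      # 1/sqrt(4)
  # metric properties on random clipped triples
  set.seed(30)
  for (i in 1:20) {
    a <- map_from_values(runif(9), 3, 3)
    b <- map_from_values(runif(9), 3, 3)
    c <- map_from_values(runif(9), 3, 3)
    expect_equal(map_distance(a, b), map_distance(b, a))
    expect_lte(map_distance(a, c),
               map_distance(a, b) + map_distance(b, c) + 1e-12)
  }
  bad <- map_from_values(runif(4), 2, 2)
  bad$channel <- 5:8
  expect_error(map_distance(z4, bad), "different electrode sets")
})

test_that("peak displacement follows grid geometry and ignores offsets", {
  a <- map_from_values(c(0, 0, 0, 0, 0, 0, 0, 0, 1), 3, 3)  # peak at (3,3)
  expect_equal(peak_displacement(a, a), 0)
  b <- map_from_values(c(1, 0, 0, 0, 0, 0, 0, 0, 0), 3, 3)  # peak at (1,1)
  expect_equal(peak_displacement(a, b), sqrt(2) * 8)
  rowpair <- map_from_values(c(0, 0, 1, 0, 0, 0, 0, 0, 0), 3, 3) # (1,3)
  expect_equal(peak_displacement(b, rowpair), 8)
  # adding a constant to both maps changes nothing
  a2 <- a; a2$fvaf <- a2$fvaf + 0.3
  b2 <- b; b2$fvaf <- b2$fvaf + 0.3
  expect_equal(peak_displacement(a2, b2), peak_displacement(a, b))
  empty <- a; empty$fvaf <- NA_real_
  expect_error(peak_displacement(a, empty), "no non-missing")
})

test_that("identical map sets give equal D_inter and D_intra and no rejection", {
  set.seed(31)
  m <- matrix(runif(16 * 10), 16, 10)
  mm <- maps_from_matrix(m, 4, 4, mode = "movement")
  ff <- maps_from_matrix(m, 4, 4, mode = "force")
  cmp <- compare_inter_intra(mm, ff)
  expect_equal(cmp$median_d_inter, cmp$median_d_intra, tolerance = 0.1)
  expect_equal(cmp$d_inter_paired, cmp$d_intra_paired, tolerance = 1e-12)
  expect_gt(cmp$test$p_value, 0.4)
  expect_equal(cmp$displacement_mm, rep(0, 10))
})

test_that("requesting n folds yields n maps per mode", {
  ses <- tiny_session()
  fe <- tiny_features()
  des <- build_lagged_design(fe, 10L)
  y <- align_target(kinematic_pc1(ses$recording$kinematics),
                    ses$recording$fs_hz, des$bin_times)
  maps <- single_electrode_maps(fe, y, n_folds = 5L)
  expect_equal(length(unique(maps$fold)), 5L)
  expect_equal(nrow(maps), 16L * 5L)
})

test_that("a planted 8-mm peak shift is recovered within 4 mm", {
  ses <- simulate_session(sim_config(n_trials = 24L, n_rows = 4L, n_cols = 4L,
                                     snr = 8, planted_peak_shift_mm = 8,
                                     seed = 33L))
  fe <- compute_band_features(ses$recording)
  des <- build_lagged_design(fe, 10L)
  mv <- align_target(kinematic_pc1(ses$recording$kinematics),
                     ses$recording$fs_hz, des$bin_times)
  fr <- align_target(ses$recording$force, ses$recording$fs_hz, des$bin_times)
  mm <- single_electrode_maps(fe, mv, "movement", n_folds = 10L)
  fm <- single_electrode_maps(fe, fr, "force", n_folds = 10L)
  cmp <- compare_inter_intra(mm, fm)
  expect_lt(abs(mean(cmp$displacement_mm) - 8), 4)
  # the planted peak electrodes attain high map values
  avg <- aggregate(fvaf ~ channel, data = mm, FUN = median)
  expect_gte(avg$fvaf[which.max(ses$truth$movement_gain_eff)],
             sort(avg$fvaf, decreasing = TRUE)[3])
})

test_that("recovered displacement grows with the planted shift", {
  shifts <- c(0, 4, 8)
  rec <- vapply(shifts, function(sh) {
    d <- vapply(1:2, function(s) {
      ses <- simulate_session(sim_config(n_trials = 12L, n_rows = 4L,
                                         n_cols = 4L, snr = 8,
                                         planted_peak_shift_mm = sh,
                                         seed = 400L + s))
      fe <- compute_band_features(ses$recording)
      des <- build_lagged_design(fe, 10L)
      mv <- align_target(kinematic_pc1(ses$recording$kinematics),
                         ses$recording$fs_hz, des$bin_times)
      fr <- align_target(ses$recording$force, ses$recording$fs_hz,
                         des$bin_times)
      mm <- single_electrode_maps(fe, mv, "movement", n_folds = 10L)
      fm <- single_electrode_maps(fe, fr, "force", n_folds = 10L)
      mean(compare_inter_intra(mm, fm)$displacement_mm)
    }, numeric(1))
    mean(d)
  }, numeric(1))
  expect_true(all(diff(rec) > 0))
})
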