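test_that("session structure follows the task protocol", {
  ses <- tiny_session()
  expect_equal(nrow(ses$trials), 10L)
  expect_equal(ncol(ses$recording$signal), 16L)
  tt <- ses$truth$true_onsets
  expect_true(all(tt$cue_time_s < tt$movement_onset_s))
  expect_true(all(tt$movement_onset_s < tt$force_onset_s))
  expect_true(all(tt$force_onset_s < tt$peak_force_time_s))
  # per-trial labels appear in order premovement < movement < force
  lab <- as.integer(ses$truth$true_mode_labels)
  t_s <- (seq_along(lab) - 1L) / ses$recording$fs_hz
  for (i in seq_len(nrow(tt))) {
    in_trial <- t_s >= tt$cue_time_s[i] & t_s < tt$force_end_s[i]
    runs <- rle(lab[in_trial])
    labeled <- runs$values[runs$values != 4L]
    expect_equal(labeled, sort(labeled))
  }
})

test_that("inter-trial delay equals the configured 1 s with zero jitter", {
  cfg <- sim_config(n_trials = 5L, n_rows = 2L, n_cols = 2L,
                    premove_sd_s = 0, move_sd_s = 0,
                    planted_peak_shift_mm = 4, iti_s = 1.0, seed = 2L)
  ses <- simulate_session(cfg)
  tt <- ses$truth$true_onsets
  gaps <- tt$cue_time_s[-1] - tt$force_end_s[-nrow(tt)]
  expect_equal(gaps, rep(1.0, 4L), tolerance = 1e-9)
})

test_that("identical seed and config give bit-identical sessions", {
  cfg <- sim_config(n_trials = 3L, n_rows = 3L, n_cols = 3L, seed = 77L,
                    planted_peak_shift_mm = 4)
  a <- simulate_session(cfg)
  b <- simulate_session(cfg)
  expect_identical(a$recording$signal, b$recording$signal)
  expect_identical(a$recording$force, b$recording$force)
  expect_identical(a$truth$latent_traces, b$truth$latent_traces)
})

test_that("planted gain maps realize the requested peak geometry", {
  m0 <- plant_gain_maps(4, 4, 4, shift_mm = 0, seed = 1)
  expect_identical(m0$movement_peak, m0$force_peak)
  m8 <- plant_gain_maps(4, 4, 4, shift_mm = 8, seed = 1)
  d <- abs(unname(m8$force_peak - m8$movement_peak))
  expect_equal(sort(d), c(0, 2))             # two sites apart along one axis
  md <- plant_gain_maps(4, 4, 4, shift_mm = sqrt(2) * 4, seed = 1)
  expect_equal(unname(abs(md$force_peak - md$movement_peak)), c(1, 1))
  # maps are unimodal with argmax at the planted site
  expect_equal(which(m8$movement == max(m8$movement)),
               (m8$movement_peak["col"] - 1) * 4 + m8$movement_peak["row"],
               ignore_attr = TRUE)
  expect_true(all(m8$movement >= 0))
})

test_that("impossible shifts are rejected with achievable alternatives", {
  expect_error(plant_gain_maps(2, 2, 4, shift_mm = 3), "achievable")
  expect_error(plant_gain_maps(1, 2, 4, shift_mm = 40), "achievable")
})

test_that("unmodulated electrodes have exactly constant planted amplitude", {
  # zero-gain sites receive no planted modulation at all (the latent drive is
  # gated by the gain maps); their band-power variance is pure
  # spectral-estimation noise from the stochastic carriers, well below the
  # modulated sites even in a short session
  cfg <- sim_config(n_trials = 6L, n_rows = 4L, n_cols = 4L, snr = Inf,
                    gain_sigma_mm = 3, seed = 11L)
  ses <- simulate_session(cfg)
  tr <- ses$truth
  gain <- tr$movement_gain_eff + tr$force_gain_eff
  flat <- which(gain < 1e-6)
  low_gain <- which(gain < 0.05)
  modulated <- which(gain > 0.5)
  expect_gt(length(low_gain), 0)
  # exact: planted log-amplitude contributions all vanish at zero-gain sites
  if (length(flat) > 0) {
    expect_true(all(abs(tr$latent_loadings_low[flat, ]) == 0))
    expect_true(all(abs(tr$latent_loadings_high[flat, ]) == 0))
  }
  fe <- compute_band_features(ses$recording)
  vari <- apply(fe$values, 2, var)
  ch_of <- fe$feature_index$channel
  expect_lt(median(vari[ch_of %in% low_gain]),
            0.5 * median(vari[ch_of %in% modulated]))
})

test_that("carriers keep >95% of their power inside the nominal band", {
  set.seed(5)
  fs <- 2000
  for (band in list(c(8, 55), c(70, 150))) {
    x <- ecogrip:::bandlimited_noise(2^15, fs, band[1], band[2])
    sp <- Mod(fft(x))^2
    f <- (seq_along(sp) - 1) * fs / length(sp)
    half <- f <= fs / 2
    inside <- f >= band[1] - 2 & f <= band[2] + 2
    expect_gt(sum(sp[half & inside]) / sum(sp[half]), 0.95)
  }
})

test_that("planted log-amplitude is exactly rank latent_dim + 2 (SVD oracle)", {
  # the log-amplitude driving each carrier is a sum of outer products:
  # movement envelope x movement gains, force envelope x force gains, and
  # latent traces x loadings -- numerical rank latent_dim + 2 exactly
  cfg <- sim_config(n_trials = 8L, n_rows = 4L, n_cols = 4L, snr = Inf,
                    latent_dim = 2L, seed = 13L)
  ses <- simulate_session(cfg)
  tr <- ses$truth
  u_hi <- 0.5 * cfg$mod_depth_high *
    (outer(tr$movement_envelope, tr$movement_gain_eff) +
       outer(tr$force_envelope, tr$force_gain_eff)) +
    0.5 * cfg$latent_strength * tr$latent_traces %*% t(tr$latent_loadings_high)
  sv <- svd(sweep(u_hi, 2, colMeans(u_hi)))$d
  k <- cfg$latent_dim + 2L
  expect_gt(sv[k], 1e-6 * sv[1])
  expect_lt(sv[k + 1], 1e-8 * sv[1])
  # the same time courses are recoverable from the top singular subspace of
  # the measured features (up to spectral-estimation noise of the carriers)
  fe <- compute_band_features(ses$recording)
  v <- sweep(fe$values, 2, colMeans(fe$values))
  keep <- apply(v, 2, sd) > 1e-3
  basis <- svd(v[, keep], nu = k)$u
  tru <- cbind(
    approx(tr$latent_times_s, tr$movement_envelope,
           xout = fe$bin_times, rule = 2)$y,
    approx(tr$latent_times_s, tr$force_envelope,
           xout = fe$bin_times, rule = 2)$y
  )
  for (j in 1:2) {
    res <- lm.fit(basis, tru[, j] - mean(tru[, j]))$residuals
    r2 <- 1 - sum(res^2) / sum((tru[, j] - mean(tru[, j]))^2)
    expect_gt(r2, 0.85)
  }
})
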