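test_that("timing identities: frequency resolution, hop, bin count", {
  fe <- tiny_features()
  expect_equal(fe$freq_resolution_hz, 2000 / 512)   # 3.90625 -> 3.9 Hz printed
  expect_equal(round(fe$freq_resolution_hz, 1), 3.9)
  steps <- diff(fe$bin_times)
  expect_equal(steps, rep(0.025, length(steps)), tolerance = 1e-12)
  # window 256 ms overlapping the previous by 231 ms gives the 25-ms hop
  expect_equal(fe$window_s - 0.231, fe$step_s, tolerance = 1e-12)
  n <- nrow(tiny_session()$recording$signal)
  expect_equal(nrow(fe$values), (n - 512) %/% 50 + 1)
})

test_that("white-noise features center on the log-of-mean normalization point", {
  # normalizing log power by the log of the MEAN power leaves the Jensen
  # offset E[log(P/EP)] = digamma(1) = -0.5772 for the exponential per-bin
  # power of stationary noise; the features must sit at that constant, with
  # no residual file-level offset beyond it
  set.seed(3)
  rec <- list(signal = matrix(rnorm(2000 * 120), ncol = 1), fs_hz = 2000)
  fe <- compute_band_features(rec)
  for (j in 1:2) {
    m <- mean(fe$values[, j])
    expect_lt(abs(m - digamma(1)), 0.02)
  }
})

test_that("band power agrees with a band-pass-filter-then-variance oracle", {
  set.seed(8)
  fs <- 2000
  x <- rnorm(fs * 240)
  win <- 512
  # un-normalized mean band power from the windowed-FFT path
  hann <- 0.5 - 0.5 * cos(2 * pi * (0:(win - 1)) / (win - 1))
  starts <- seq(0, length(x) - win, by = 50)
  freqs <- (0:(win / 2)) * fs / win
  sel <- freqs >= 70 & freqs <= 150
  pw <- vapply(starts, function(s) {
    sp <- Mod(fft(x[s + 1:win] * hann))^2
    mean(sp[1:(win / 2 + 1)][sel])
  }, numeric(1))
  # window-gain-corrected mean power per bin, converted to a band variance:
  # var_band = n_band_bins * 2 * mean(P) / (N * sum(w^2))
  fft_band_var <- mean(pw) * sum(sel) * 2 / (win * sum(hann^2))
  # oracle: brick-wall band-pass over the same effective band (bin centers
  # +/- half a bin), then take the variance directly
  half_bin <- fs / win / 2
  lo <- min(freqs[sel]) - half_bin
  hi <- max(freqs[sel]) + half_bin
  X <- fft(x)
  f <- c(0:(length(x) %/% 2), -((length(x) - length(x) %/% 2 - 1):1)) *
    fs / length(x)
  xf <- Re(fft(X * (abs(f) >= lo & abs(f) <= hi), inverse = TRUE)) / length(x)
  expect_equal(fft_band_var, var(xf), tolerance = 0.01)
})

test_that("delaying the input by whole hops shifts feature rows", {
  set.seed(4)
  x <- rnorm(2000 * 10)
  k <- 3L                                     # delay by k hops = k*50 samples
  rec1 <- list(signal = matrix(x, ncol = 1), fs_hz = 2000)
  rec2 <- list(signal = matrix(c(rep(0, k * 50), x), ncol = 1), fs_hz = 2000)
  f1 <- compute_band_features(rec1)
  f2 <- compute_band_features(rec2)
  n <- nrow(f1$values)
  # normalization constants differ slightly (file mean includes the padding),
  # but the band features are differences of logs so rows must match closely
  expect_equal(f2$values[(k + 1):(n), ], f1$values[1:(n - k), ],
               tolerance = 0.05)
})

test_that("lagged design has the documented geometry", {
  fe <- tiny_features()
  des <- build_lagged_design(fe, 10L)
  expect_equal(ncol(des$values), 2 * 16 * 10)    # 2 bands x electrodes x lags
  expect_equal(nrow(des$values), nrow(fe$values) - 9L)
  # row t concatenates rows t, t-1, ..., t-9
  expect_equal(des$values[1, 1:32], fe$values[10, ], ignore_attr = TRUE)
  expect_equal(des$values[1, 33:64], fe$values[9, ], ignore_attr = TRUE)
  d1 <- build_lagged_design(fe, 1L)
  expect_equal(d1$values, fe$values, ignore_attr = TRUE)
  expect_error(build_lagged_design(fe, nrow(fe$values) + 1L), "exceeds")
})

test_that("causality: a lagged row ignores everything after its bin", {
  fe <- tiny_features()
  des <- build_lagged_design(fe, 5L)
  t_mid <- 100L
  fe2 <- fe
  fe2$values[(t_mid + 5L):nrow(fe2$values), ] <-
    fe2$values[(t_mid + 5L):nrow(fe2$values), ] + 100
  des2 <- build_lagged_design(fe2, 5L)
  expect_identical(des$values[t_mid, ], des2$values[t_mid, ])
})

test_that("constant features produce identical design rows", {
  fe <- tiny_features()
  fe$values <- matrix(2.5, 50, 4)
  des <- build_lagged_design(fe, 3L)
  expect_true(all(des$values == 2.5))
})

test_that("band validation rejects unresolvable bands and bad samples", {
  rec <- list(signal = matrix(rnorm(4000), ncol = 1), fs_hz = 2000)
  expect_error(
    compute_band_features(rec, bands = list(band_definition("hf", 1500, 1600))),
    "no resolvable")
  rec$signal[100, 1] <- NA
  expect_error(compute_band_features(rec), "non-finite sample in channel 1")
})

test_that("event-aligned rasters align to planted force onsets and sort rows", {
  ses <- tiny_session()
  fe <- tiny_features()
  tt <- truth_trials(ses)
  # pick the force-gain peak electrode's high-band feature
  pk <- which.max(ses$truth$force_gain_eff)
  col <- fe$feature_index$column[fe$feature_index$channel == pk &
                                   fe$feature_index$band == "high"]
  r <- event_aligned_raster(fe, col, tt$force_onset_s, pre_s = 0.6, post_s = 0.6)
  rel <- attr(r, "rel_times_s")
  # mean high-band trace rises at force onset: post-onset mean well above pre
  pre <- rowMeans(r[, rel < -0.2])
  post <- rowMeans(r[, rel > 0.1 & rel < 0.45])
  expect_gt(mean(post - pre), 0.5)
  # transition column within one bin of the onset: largest jump of the mean
  avg <- colMeans(r)
  jump <- which.max(diff(avg))
  expect_lte(abs(rel[jump] - 0), 0.1 + 1e-9)
  # sorting contract
  key <- tt$force_onset_s - tt$movement_onset_s
  rs <- event_aligned_raster(fe, col, tt$force_onset_s, 0.6, 0.6, sort_key = key)
  expect_equal(attr(rs, "events"), order(key))
  # zero-variance guard
  fe0 <- fe
  fe0$values[, col] <- 1
  r0 <- event_aligned_raster(fe0, col, tt$force_onset_s, 0.4, 0.4)
  expect_true(all(r0 == 0))
})
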