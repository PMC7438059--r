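test_that("vector angles hit the exact identities and invariances", {
  expect_equal(neural_vector_angle(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(neural_vector_angle(c(1, 0), c(0, 1)), 90)
  expect_equal(neural_vector_angle(c(1, 2), c(-1, -2)), 180)
  expect_true(is.na(neural_vector_angle(c(0, 0), c(1, 1))))
  # scale invariance
  set.seed(50)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(6)
    expect_equal(neural_vector_angle(a, b),
                 neural_vector_angle(3.7 * a, 0.2 * b), tolerance = 1e-10)
  }
})

test_that("separable trace groups cluster perfectly and k = 3 wins the sweep", {
  set.seed(51)
  flat <- matrix(rnorm(8 * 40, sd = 0.01), 8)
  up <- matrix(rep(sin(seq(0, pi, length.out = 40)), each = 8), 8) +
    matrix(rnorm(8 * 40, sd = 0.01), 8)
  down <- -up + matrix(rnorm(8 * 40, sd = 0.01), 8)
  traces <- rbind(flat, up, down)
  bands <- rep(c("low", "high", "low"), each = 8)
  cl <- select_feature_clusters(traces, k = 3, seed = 1, bands = bands)
  expect_equal(length(unique(cl$cluster[1:8])), 1L)
  expect_equal(length(unique(cl$cluster[9:16])), 1L)
  expect_equal(length(unique(cl$cluster[17:24])), 1L)
  expect_gt(mean(cl$silhouette), 0.9)
  sil <- vapply(2:5, function(k) {
    select_feature_clusters(traces, k = k, seed = 1, bands = bands)$mean_silhouette
  }, numeric(1))
  expect_equal(which.max(sil) + 1L, 3L)
})

test_that("a session with homogeneous locking selects one low and one high cluster", {
  # structured session: modulated sites locked to both events with equal
  # band depths, sharp gain peaks so the rest of the grid stays quiet --
  # the clusters should come out as {well-modulated low, well-modulated
  # high, poorly modulated remainder}
  cfg <- sim_config(n_trials = 16L, n_rows = 6L, n_cols = 4L, snr = 6,
                    lock_probs = c(movement = 0, force = 0, both = 1),
                    mod_depth_low = 1.2, gain_sigma_mm = 3.5,
                    seed = 52L)
  ses <- simulate_session(cfg)
  fe <- compute_band_features(ses$recording)
  tt <- truth_trials(ses)
  w <- suppressWarnings(peri_event_windows(fe, tt$force_onset_s))
  cl <- select_feature_clusters(trial_average_features(w), k = 3, seed = 1)
  expect_setequal(cl$tags, c("low", "high"))
})

test_that("NVA time course: smoothing span, reference self-similarity, range", {
  set.seed(53)
  n_tr <- 6L; T_len <- 61L; n_feat <- 8L
  w <- list(values = array(0, c(n_tr, T_len, n_feat)),
            rel_times_s = seq(-1, 0.5, by = 0.025),
            trials = 1:n_tr,
            feature_index = tibble::tibble(column = 1:n_feat,
                                           channel = rep(1:4, each = 2),
                                           band = rep(c("low", "high"), 4)),
            step_s = 0.025)
  class(w) <- "trial_windows"
  # constant positive vectors: every angle should be ~0
  for (i in 1:n_tr) w$values[i, , ] <- matrix(1 + (1:n_feat) / 10, T_len,
                                              n_feat, byrow = TRUE)
  clus <- list(cluster = rep(c(1L, 2L), each = 4L), selected = c(1L, 2L),
               tags = c("low", "high"))
  trials <- tibble::tibble(trial = 1:n_tr, cue_time_s = -1.2,
                           movement_onset_s = -0.4, force_onset_s = 0,
                           peak_force_time_s = 0.35)
  res <- nva_time_course(w, clus, trials)
  expect_equal(res$smooth_span_s, 0.125)      # five 25-ms bins
  expect_lt(max(res$angles$theta, na.rm = TRUE), 1)
  expect_true(all(res$angles$theta >= 0 & res$angles$theta <= 180,
                  na.rm = TRUE))
  # permuting features within a cluster leaves the angles unchanged
  w2 <- w
  w2$values <- w$values[, , c(4:1, 5:8)]
  res2 <- nva_time_course(w2, clus, trials)
  expect_equal(res$angles$theta, res2$angles$theta)
})

test_that("planted high-band ramp makes the angle peak before force onset", {
  ses <- tiny_session()
  fe <- tiny_features()
  tt <- truth_trials(ses)
  w <- suppressWarnings(peri_event_windows(fe, tt$force_onset_s))
  keep <- tt[w$trials, ]
  cl <- select_feature_clusters(trial_average_features(w), k = 3, seed = 2)
  res <- nva_time_course(w, cl, keep)
  hi <- res$angles[res$angles$band == "high", ]
  avg <- aggregate(theta ~ rel_time_s, data = hi, FUN = mean)
  # the angle is large before movement, small near peak force
  pre <- mean(avg$theta[avg$rel_time_s < -1])
  ref <- mean(avg$theta[avg$rel_time_s > 0.2 & avg$rel_time_s < 0.45])
  expect_gt(pre - ref, 20)
})

test_that("mode comparison is calibrated under the null and powered when planted", {
  n_null_seeds <- 100L   # enough replicates to pin the type-I rate
  n_seeds <- 20L
  make_result <- function(seed, planted) {
    set.seed(seed)
    n_tr <- 12L
    rel <- seq(-1.5, 0.75, by = 0.025)
    trials <- tibble::tibble(trial = 1:n_tr, cue_time_s = -1.3,
                             movement_onset_s = -0.5, force_onset_s = 0,
                             peak_force_time_s = 0.35)
    rows <- lapply(1:n_tr, function(i) {
      theta <- if (planted) {
        90 + 40 * (rel >= -0.5 & rel < 0) - 60 * (rel >= 0) + rnorm(length(rel), sd = 8)
      } else {
        90 + rnorm(length(rel), sd = 8)
      }
      tibble::tibble(trial = i, band = "high", rel_time_s = rel, theta = theta)
    })
    structure(list(angles = do.call(rbind, rows), smooth_bins = 5L,
                   smooth_span_s = 0.125, ref_s = 0.25),
              class = "nva_result")
  }
  trials <- tibble::tibble(trial = 1:12, cue_time_s = -1.3,
                           movement_onset_s = -0.5, force_onset_s = 0,
                           peak_force_time_s = 0.35)
  p_null <- vapply(seq_len(n_null_seeds), function(s) {
    compare_modes_nva(make_result(600L + s, FALSE), trials)$p_value
  }, numeric(1))
  expect_gte(mean(p_null > 0.05), 0.9)
  p_alt <- vapply(seq_len(n_seeds), function(s) {
    compare_modes_nva(make_result(700L + s, TRUE), trials)$p_value
  }, numeric(1))
  expect_gte(mean(p_alt < 0.05), 0.9)
  # two-mode degenerate input still runs, flagged
  res2 <- make_result(1L, TRUE)
  res2$angles <- res2$angles[res2$angles$rel_time_s < 0, ]
  out <- compare_modes_nva(res2, trials)
  expect_true(out$flagged)
  expect_true(is.finite(out$p_value))
})
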