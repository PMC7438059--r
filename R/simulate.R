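#' Simulation configuration for a synthetic movement-force session
#'
#' Bundles every knob of the synthetic session generator. Defaults emulate the
#' study conditions of a sequential movement-force finger task recorded with a
#' high-density ECoG grid: 2 kHz sampling, 8x8 grid at 4-mm pitch, self-paced
#' flexion after a cue, then isometric force to a random target, with a 1-s
#' inter-trial delay.
#'
#' @param n_trials number of trials.
#' @param n_rows,n_cols electrode grid dimensions.
#' @param pitch_mm interelectrode spacing in millimetres.
#' @param fs_hz sampling rate of all traces, Hz.
#' @param premove_mean_s,premove_sd_s mean and jitter SD of the premovement
#'   (cue-to-flexion) duration, seconds.
#' @param move_mean_s,move_sd_s mean and jitter SD of the movement
#'   (flexion-to-contact) duration, seconds.
#' @param dur_floor_s hard floor for jittered durations, seconds.
#' @param force_dur_s duration of the isometric force hold, seconds.
#' @param iti_s delay between the end of the force window and the next cue.
#' @param planted_peak_shift_mm Euclidean displacement between the movement and
#'   force gain-map peaks. Must be realizable on the grid.
#' @param latent_dim number of ground-truth shared latent factors.
#' @param snr ratio of carrier RMS to additive white-noise SD; `Inf` disables
#'   additive noise.
#' @param lock_probs probabilities that an electrode's band modulation is
#'   time-locked to movement onset, force onset, or both.
#' @param n_glove_sensors number of simulated glove sensors.
#' @param sensor_noise_sd additive noise SD on each glove sensor trace.
#' @param mod_depth_high,mod_depth_low peak log-amplitude modulation depths of
#'   the high (increase) and low (decrease) frequency carriers.
#' @param gain_sigma_mm spatial SD of the planted Gaussian gain bumps, mm
#'   (smaller values concentrate modulation near the peaks and leave the rest
#'   of the grid unmodulated).
#' @param latent_strength log-amplitude scale of the shared latent drive.
#' @param seed integer seed; fully determines the session.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_trials = 60L,
                       n_rows = 8L, n_cols = 8L, pitch_mm = 4,
                       fs_hz = 2000,
                       premove_mean_s = 0.8, premove_sd_s = 0.15,
                       move_mean_s = 0.4, move_sd_s = 0.15,
                       dur_floor_s = 0.1,
                       force_dur_s = 1.0,
                       iti_s = 1.0,
                       planted_peak_shift_mm = 8,
                       latent_dim = 3L,
                       snr = 2,
                       lock_probs = c(movement = 0.3, force = 0.3, both = 0.4),
                       n_glove_sensors = 4L,
                       sensor_noise_sd = 0.02,
                       mod_depth_high = 1.2,
                       mod_depth_low = 0.8,
                       latent_strength = 0.4,
                       gain_sigma_mm = 6,
                       seed = 1L) {
  cfg <- list(
    n_trials = as.integer(n_trials), n_rows = as.integer(n_rows),
    n_cols = as.integer(n_cols), pitch_mm = pitch_mm, fs_hz = fs_hz,
    premove_mean_s = premove_mean_s, premove_sd_s = premove_sd_s,
    move_mean_s = move_mean_s, move_sd_s = move_sd_s,
    dur_floor_s = dur_floor_s, force_dur_s = force_dur_s, iti_s = iti_s,
    planted_peak_shift_mm = planted_peak_shift_mm,
    latent_dim = as.integer(latent_dim), snr = snr,
    lock_probs = lock_probs, n_glove_sensors = as.integer(n_glove_sensors),
    sensor_noise_sd = sensor_noise_sd,
    mod_depth_high = mod_depth_high, mod_depth_low = mod_depth_low,
    latent_strength = latent_strength, gain_sigma_mm = gain_sigma_mm,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stop_if(cfg$n_trials < 1L, "n_trials must be >= 1")
  stop_if(cfg$n_rows < 1L || cfg$n_cols < 1L, "grid must have at least one site")
  stop_if(cfg$fs_hz <= 0, "fs_hz must be positive")
  for (f in c("premove_mean_s", "move_mean_s", "force_dur_s", "iti_s",
              "dur_floor_s", "pitch_mm")) {
    stop_if(cfg[[f]] <= 0, f, " must be positive")
  }
  stop_if(cfg$premove_sd_s < 0 || cfg$move_sd_s < 0, "duration SDs must be >= 0")
  stop_if(cfg$snr <= 0, "snr must be positive (Inf allowed)")
  stop_if(abs(sum(cfg$lock_probs) - 1) > 1e-8 || length(cfg$lock_probs) != 3L,
          "lock_probs must be three probabilities summing to 1")
  stop_if(cfg$latent_dim < 0L, "latent_dim must be >= 0")
  invisible(cfg)
}

#' Plant smooth unimodal gain maps with a known peak displacement
#'
#' Builds two Gaussian-bump gain maps on an electrode grid whose argmax sites
#' are exactly `shift_mm` apart (Euclidean distance in millimetres). The
#' movement peak is placed as centrally as the requested shift allows; the
#' force peak is offset from it.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param pitch_mm interelectrode spacing, mm.
#' @param shift_mm requested peak displacement; must equal the distance between
#'   two grid sites.
#' @param seed integer seed controlling placement among equally central options.
#' @param sigma_mm spatial SD of each Gaussian bump, mm.
#' @return A list with `movement` and `force` gain matrices
#'   (`n_rows` x `n_cols`, non-negative, max 1), the peak `(row, col)` of each,
#'   and the realized `shift_mm`.
#' @export
plant_gain_maps <- function(n_rows, n_cols, pitch_mm = 4, shift_mm = 8,
                            seed = 1L, sigma_mm = 1.5 * pitch_mm) {
  stop_if(n_rows < 1 || n_cols < 1, "grid must have at least one site")
  dr <- rep(-(n_rows - 1L):(n_rows - 1L), times = 2L * n_cols - 1L)
  dc <- rep(-(n_cols - 1L):(n_cols - 1L), each = 2L * n_rows - 1L)
  dist_mm <- pitch_mm * sqrt(dr^2 + dc^2)
  ok <- which(abs(dist_mm - shift_mm) < 1e-6)
  if (length(ok) == 0L) {
    ach <- sort(unique(round(dist_mm, 3)))
    stop("planted peak shift ", shift_mm, " mm is not realizable on a ",
         n_rows, "x", n_cols, " grid with ", pitch_mm,
         "-mm pitch; achievable shifts (mm): ",
         paste(utils::head(ach, 30L), collapse = ", "),
         if (length(ach) > 30L) ", ..." else "", call. = FALSE)
  }
  # candidate placements: movement peak (r1,c1) s.t. force peak stays on grid
  cand <- do.call(rbind, lapply(ok, function(i) {
    r1 <- seq_len(n_rows); c1 <- seq_len(n_cols)
    g <- expand.grid(r1 = r1, c1 = c1)
    g$r2 <- g$r1 + dr[i]; g$c2 <- g$c1 + dc[i]
    g[g$r2 >= 1 & g$r2 <= n_rows & g$c2 >= 1 & g$c2 <= n_cols, ]
  }))
  stop_if(nrow(cand) == 0L,
          "grid too small to place both planted peaks at shift ", shift_mm, " mm")
  ctr <- c((n_rows + 1) / 2, (n_cols + 1) / 2)
  score <- (cand$r1 - ctr[1])^2 + (cand$c1 - ctr[2])^2 +
    (cand$r2 - ctr[1])^2 + (cand$c2 - ctr[2])^2
  best <- which(score <= min(score) + 1e-9)
  set.seed(seed)
  pick <- cand[best[sample.int(length(best), 1L)], ]
  bump <- function(r0, c0) {
    d2 <- outer((seq_len(n_rows) - r0)^2, (seq_len(n_cols) - c0)^2, `+`) * pitch_mm^2
    exp(-d2 / (2 * sigma_mm^2))
  }
  list(movement = bump(pick$r1, pick$c1),
       force = bump(pick$r2, pick$c2),
       movement_peak = c(row = pick$r1, col = pick$c1),
       force_peak = c(row = pick$r2, col = pick$c2),
       shift_mm = pitch_mm * sqrt((pick$r2 - pick$r1)^2 + (pick$c2 - pick$c1)^2),
       pitch_mm = pitch_mm, sigma_mm = sigma_mm)
}

# band-limited Gaussian noise, unit RMS, via FFT masking (padded to a fast length)
bandlimited_noise <- function(n, fs, lo_hz, hi_hz) {
  m <- stats::nextn(n, c(2L, 3L, 5L))
  x <- stats::rnorm(m)
  f <- c(seq_len(m %/% 2 + 1L) - 1L, -rev(seq_len(m - m %/% 2 - 1L))) * fs / m
  mask <- abs(f) >= lo_hz & abs(f) <= hi_hz
  y <- Re(stats::fft(stats::fft(x) * mask, inverse = TRUE)) / m
  y <- y[seq_len(n)]
  y / stats::sd(y)
}

# raised-cosine ramp from 0 to 1 over `rise` seconds, evaluated at sample times
ramp_segment <- function(t, t0, rise) {
  u <- clamp((t - t0) / rise, 0, 1)
  0.5 - 0.5 * cos(pi * u)
}

#' Simulate a complete movement-force session with known ground truth
#'
#' Generates multichannel surface potentials as amplitude-modulated
#' band-limited noise carriers (one 8-55 Hz, one 70-150 Hz per electrode),
#' glove-like kinematic sensor traces, a force trace with per-trial random
#' targets, and per-trial cue times. Each electrode's log carrier amplitude is
#' driven by smooth gain-map-weighted envelopes locked to movement and/or force
#' onset (high band up, low band down) plus shared low-dimensional latent
#' traces, so the downstream spectral, spatial, and latent analyses all have a
#' known answer.
#'
#' @param config a [sim_config()].
#' @return A list with components `recording` (class `ecog_recording`: signal
#'   matrix samples x channels, `fs_hz`, channel table, `kinematics`, `force`,
#'   `cue_times_s`), `trials` (tibble: trial, cue time, force target), and
#'   `truth` (class `ecog_ground_truth`: gain maps, locking assignment, latent
#'   traces on a 25-ms grid, per-sample mode labels, true per-trial onsets).
#' @export
simulate_session <- function(config = sim_config()) {
  validate_sim_config(config)
  cfg <- config
  maps <- plant_gain_maps(cfg$n_rows, cfg$n_cols, cfg$pitch_mm,
                          cfg$planted_peak_shift_mm, seed = cfg$seed,
                          sigma_mm = cfg$gain_sigma_mm)
  set.seed(cfg$seed + 1L)
  n_tr <- cfg$n_trials
  fs <- cfg$fs_hz

  pre_dur <- rtnorm_floor(n_tr, cfg$premove_mean_s, cfg$premove_sd_s, cfg$dur_floor_s)
  mov_dur <- rtnorm_floor(n_tr, cfg$move_mean_s, cfg$move_sd_s, cfg$dur_floor_s)
  target <- stats::runif(n_tr, 0.2, 1.0)

  lead_in <- 0.5
  cue <- numeric(n_tr)
  cue[1] <- lead_in
  mvt_on <- frc_on <- frc_end <- numeric(n_tr)
  for (i in seq_len(n_tr)) {
    mvt_on[i] <- cue[i] + pre_dur[i]
    frc_on[i] <- mvt_on[i] + mov_dur[i]
    frc_end[i] <- frc_on[i] + cfg$force_dur_s
    if (i < n_tr) cue[i + 1] <- frc_end[i] + cfg$iti_s
  }
  total_s <- frc_end[n_tr] + cfg$iti_s
  n_samp <- ceiling(total_s * fs)
  t_s <- (seq_len(n_samp) - 1L) / fs

  rise_mv <- 0.15; fall_mv <- 0.30
  rise_f <- 0.15; hump_at <- 0.35; fall_f <- 0.15
  e_mv <- numeric(n_samp)          # flexion-state envelope (0..1)
  f_shape <- numeric(n_samp)       # unit force profile (peaks at hump_at)
  for (i in seq_len(n_tr)) {
    seg <- which(t_s >= mvt_on[i] & t_s < frc_end[i] + fall_mv + 0.05)
    ts <- t_s[seg]
    up <- ramp_segment(ts, mvt_on[i], rise_mv)
    down <- 1 - ramp_segment(ts, frc_end[i], fall_mv)
    e_mv[seg] <- pmax(e_mv[seg], pmin(up, down))
    seg <- which(t_s >= frc_on[i] & t_s < frc_end[i] + fall_f + 0.05)
    ts <- t_s[seg]
    # rise to a mild overshoot peaking hump_at after onset, settle to 1, drop
    base <- ramp_segment(ts, frc_on[i], rise_f)
    hump <- 1 + 0.08 * exp(-0.5 * ((ts - (frc_on[i] + hump_at)) / 0.08)^2)
    down <- 1 - ramp_segment(ts, frc_end[i], fall_f)
    f_shape[seg] <- pmax(f_shape[seg], base * hump * down)
  }
  # per-trial scaling of the force trace and of the neural force envelope
  force <- numeric(n_samp)
  e_f_amp <- numeric(n_samp)
  for (i in seq_len(n_tr)) {
    seg <- which(t_s >= frc_on[i] & t_s < frc_end[i] + fall_f + 0.05)
    force[seg] <- target[i] * f_shape[seg]
    e_f_amp[seg] <- (0.5 + 0.5 * target[i]) * pmin(f_shape[seg], 1)
  }
  peak_force_time <- frc_on + hump_at

  # shared latent traces on a 25-ms grid, smoothed Gaussian noise, unit SD
  lat_step <- 0.025
  t_lat <- seq(0, (n_samp - 1L) / fs, by = lat_step)
  n_lat <- length(t_lat)
  latent <- matrix(0, n_lat, cfg$latent_dim)
  if (cfg$latent_dim > 0L) {
    kern <- stats::dnorm(-12:12, sd = 4)
    kern <- kern / sum(kern)
    for (k in seq_len(cfg$latent_dim)) {
      z <- stats::rnorm(n_lat + 48L)
      z <- as.numeric(stats::filter(z, kern, sides = 2))
      z <- z[25L:(24L + n_lat)]
      latent[, k] <- (z - mean(z)) / stats::sd(z)
    }
  }

  n_ch <- cfg$n_rows * cfg$n_cols
  # channel table, row-major ordering
  grid <- expand.grid(col = seq_len(cfg$n_cols), row = seq_len(cfg$n_rows))
  channels <- tibble::tibble(
    channel = seq_len(n_ch),
    row = grid$row, col = grid$col,
    x_mm = (grid$col - 1) * cfg$pitch_mm,
    y_mm = (grid$row - 1) * cfg$pitch_mm,
    include = TRUE
  )
  g_mv <- maps$movement[cbind(channels$row, channels$col)]
  g_f <- maps$force[cbind(channels$row, channels$col)]

  lock <- sample(c("movement", "force", "both"), n_ch, replace = TRUE,
                 prob = cfg$lock_probs)
  peak_mv_ch <- which(channels$row == maps$movement_peak["row"] &
                        channels$col == maps$movement_peak["col"])
  peak_f_ch <- which(channels$row == maps$force_peak["row"] &
                       channels$col == maps$force_peak["col"])
  lock[c(peak_mv_ch, peak_f_ch)] <- "both"
  g_mv_eff <- g_mv * (lock %in% c("movement", "both"))
  g_f_eff <- g_f * (lock %in% c("force", "both"))

  # latent loadings gated by total planted gain so unmodulated sites stay silent
  gate <- g_mv_eff + g_f_eff
  if (max(gate) > 0) gate <- gate / max(gate)
  W_lo <- W_hi <- matrix(0, n_ch, cfg$latent_dim)
  if (cfg$latent_dim > 0L) {
    W_lo <- matrix(stats::rnorm(n_ch * cfg$latent_dim), n_ch) /
      sqrt(cfg$latent_dim) * gate
    W_hi <- matrix(stats::rnorm(n_ch * cfg$latent_dim), n_ch) /
      sqrt(cfg$latent_dim) * gate
  }
  lat_samp <- matrix(0, n_samp, cfg$latent_dim)
  if (cfg$latent_dim > 0L) {
    for (k in seq_len(cfg$latent_dim)) {
      lat_samp[, k] <- stats::approx(t_lat, latent[, k], xout = t_s, rule = 2)$y
    }
  }

  noise_sd <- if (is.finite(cfg$snr)) sqrt(2) / cfg$snr else 0
  signal <- matrix(0, n_samp, n_ch)
  for (ch in seq_len(n_ch)) {
    u_evt <- g_mv_eff[ch] * e_mv + g_f_eff[ch] * e_f_amp
    u_lat_lo <- if (cfg$latent_dim > 0L) drop(lat_samp %*% W_lo[ch, ]) else 0
    u_lat_hi <- if (cfg$latent_dim > 0L) drop(lat_samp %*% W_hi[ch, ]) else 0
    amp_lo <- exp(-0.5 * cfg$mod_depth_low * u_evt + 0.5 * cfg$latent_strength * u_lat_lo)
    amp_hi <- exp(0.5 * cfg$mod_depth_high * u_evt + 0.5 * cfg$latent_strength * u_lat_hi)
    sig <- bandlimited_noise(n_samp, fs, 8, 55) * amp_lo +
      bandlimited_noise(n_samp, fs, 70, 150) * amp_hi
    if (noise_sd > 0) sig <- sig + stats::rnorm(n_samp, sd = noise_sd)
    signal[, ch] <- sig
  }

  load_s <- stats::runif(cfg$n_glove_sensors, 0.6, 1.2)
  kinematics <- vapply(seq_len(cfg$n_glove_sensors), function(s) {
    load_s[s] * e_mv + stats::rnorm(n_samp, sd = cfg$sensor_noise_sd)
  }, numeric(n_samp))

  # ground-truth per-sample mode labels (force mode = first 0.5 s of force)
  labels <- rep("unlabeled", n_samp)
  for (i in seq_len(n_tr)) {
    labels[t_s >= cue[i] & t_s < mvt_on[i]] <- "premovement"
    labels[t_s >= mvt_on[i] & t_s < frc_on[i]] <- "movement"
    labels[t_s >= frc_on[i] & t_s < frc_on[i] + 0.5] <- "force"
  }
  labels <- factor(labels, levels = c("premovement", "movement", "force", "unlabeled"))

  recording <- structure(list(
    signal = signal, fs_hz = fs, channels = channels,
    kinematics = kinematics, force = force, cue_times_s = cue
  ), class = "ecog_recording")

  trials <- tibble::tibble(trial = seq_len(n_tr), cue_time_s = cue,
                           force_target = target)

  truth <- structure(list(
    movement_gain_map = g_mv, force_gain_map = g_f,
    movement_gain_eff = g_mv_eff, force_gain_eff = g_f_eff,
    gain_matrices = maps[c("movement", "force")],
    movement_peak = maps$movement_peak, force_peak = maps$force_peak,
    planted_shift_mm = maps$shift_mm,
    lock = lock,
    latent_loadings_low = W_lo, latent_loadings_high = W_hi,
    latent_times_s = t_lat, latent_traces = latent,
    envelope_times_s = t_lat,
    movement_envelope = stats::approx(t_s, e_mv, xout = t_lat, rule = 2)$y,
    force_envelope = stats::approx(t_s, e_f_amp, xout = t_lat, rule = 2)$y,
    true_mode_labels = labels,
    true_onsets = tibble::tibble(
      trial = seq_len(n_tr), cue_time_s = cue,
      movement_onset_s = mvt_on, force_onset_s = frc_on,
      peak_force_time_s = peak_force_time, force_end_s = frc_end,
      force_target = target
    )
  ), class = "ecog_ground_truth")

  list(recording = recording, trials = trials, truth = truth, config = cfg)
}

#' @export
print.ecog_recording <- function(x, ...) {
  cat("<ecog_recording> ", ncol(x$signal), " channels x ",
      nrow(x$signal), " samples @ ", x$fs_hz, " Hz (",
      round(nrow(x$signal) / x$fs_hz, 1), " s), ",
      length(x$cue_times_s), " cues\n", sep = "")
  invisible(x)
}
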