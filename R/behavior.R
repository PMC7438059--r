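#' First principal component of the glove sensor traces
#'
#' Reduces the index-finger glove sensors to one movement signal: the first
#' principal component over time (PCA on the session), sign-oriented so that
#' flexion deflections are positive.
#'
#' @param sensor_traces matrix samples x sensors (at least one sensor).
#' @return Numeric movement signal, one value per sample, with attributes
#'   `rotation` (sensor loadings) and `var_explained` (PC1 variance fraction).
#' @export
kinematic_pc1 <- function(sensor_traces) {
  x <- as.matrix(sensor_traces)
  stop_if(ncol(x) < 1L, "need at least one sensor trace")
  sds <- apply(x, 2, stats::sd)
  stop_if(any(sds == 0), "zero-variance sensor trace(s): ",
          paste(which(sds == 0), collapse = ", "))
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  s <- p$x[, 1]
  # flexion excursions are one-sided away from the resting baseline:
  # orient so the larger excursion from the median is positive
  if ((max(s) - stats::median(s)) < (stats::median(s) - min(s))) {
    s <- -s
    p$rotation[, 1] <- -p$rotation[, 1]
  }
  attr(s, "rotation") <- p$rotation[, 1]
  attr(s, "var_explained") <- p$sdev[1]^2 / sum(p$sdev^2)
  s
}

#' Detect movement and force onsets for each cued trial
#'
#' Movement onset: first time after the cue at which the movement signal
#' exceeds its pre-cue baseline mean + `thresh_sd` baseline SDs and stays above
#' threshold for at least `sustain_s`. Force onset: first time the force trace
#' exceeds `contact_frac` of the session's maximum force. Peak force time is
#' the force argmax within the trial window. Trials with no qualifying
#' crossing, or with onsets out of order, are flagged invalid.
#'
#' @param movement numeric movement signal (e.g. [kinematic_pc1()]).
#' @param force numeric force trace, same length.
#' @param cue_times sorted cue times, seconds.
#' @param fs_hz sampling rate of both traces.
#' @param baseline_s pre-cue baseline length used for the threshold, seconds.
#' @param thresh_sd movement threshold in baseline SDs.
#' @param sustain_s minimum supra-threshold duration, seconds.
#' @param contact_frac force contact threshold as a fraction of session max.
#' @param timeout_s force-matching timeout after force onset, seconds.
#' @param force_targets optional per-trial targets; a trial is `matched` when
#'   force reaches 95% of its target within the timeout, else `timeout`.
#' @return A tibble (class `trial_table`) with one row per cue: trial, cue
#'   time, movement/force onsets, peak force time and value, outcome, valid.
#' @export
detect_onsets <- function(movement, force, cue_times, fs_hz,
                          baseline_s = 0.3, thresh_sd = 3, sustain_s = 0.05,
                          contact_frac = 0.02, timeout_s = 2,
                          force_targets = NULL) {
  stop_if(length(movement) != length(force),
          "movement and force traces must have equal length")
  stop_if(is.unsorted(cue_times, strictly = TRUE), "cue times must be sorted")
  n <- length(movement)
  t_end <- (n - 1L) / fs_hz
  sustain_n <- max(1L, round(sustain_s * fs_hz))
  fmax <- max(force)
  contact_thr <- contact_frac * fmax

  rows <- lapply(seq_along(cue_times), function(i) {
    cue <- cue_times[i]
    w0 <- floor(cue * fs_hz) + 1L
    w1 <- if (i < length(cue_times)) floor(cue_times[i + 1] * fs_hz) else n
    b0 <- max(1L, floor((cue - baseline_s) * fs_hz) + 1L)
    base <- movement[b0:max(b0, w0 - 1L)]
    thr <- mean(base) + thresh_sd * stats::sd(base)
    if (!is.finite(thr)) thr <- mean(base)
    seg <- movement[w0:w1]
    above <- seg > thr
    mvt_idx <- NA_integer_
    if (any(above)) {
      r <- rle(above)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      hit <- which(r$values & r$lengths >= sustain_n)
      if (length(hit) > 0L) mvt_idx <- starts[hit[1]]
    }
    frc_idx <- NA_integer_
    fseg <- force[w0:w1]
    cross <- which(fseg > contact_thr)
    if (length(cross) > 0L) frc_idx <- cross[1]
    peak_idx <- which.max(fseg)
    mvt_t <- if (is.na(mvt_idx)) NA_real_ else (w0 + mvt_idx - 2L) / fs_hz
    frc_t <- if (is.na(frc_idx)) NA_real_ else (w0 + frc_idx - 2L) / fs_hz
    peak_t <- (w0 + peak_idx - 2L) / fs_hz
    valid <- !is.na(mvt_t) && !is.na(frc_t) && cue < mvt_t && mvt_t < frc_t &&
      frc_t <= peak_t
    outcome <- NA_character_
    if (valid) {
      tgt <- if (!is.null(force_targets)) force_targets[i] else max(fseg)
      in_time <- fseg[frc_idx:min(length(fseg), frc_idx + round(timeout_s * fs_hz))]
      outcome <- if (max(in_time) >= 0.95 * tgt) "matched" else "timeout"
    }
    tibble::tibble(
      trial = i, cue_time_s = cue,
      movement_onset_s = mvt_t, force_onset_s = frc_t,
      peak_force_time_s = peak_t, peak_force = fseg[peak_idx],
      force_target = if (!is.null(force_targets)) force_targets[i] else NA_real_,
      outcome = outcome, valid = valid
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("trial_table", class(out))
  attr(out, "record_end_s") <- t_end
  out
}

#' Label each feature bin with a behavioral mode
#'
#' Per valid trial, bins (by center time, half-open intervals) in
#' `[cue, movement_onset)` are premovement, `[movement_onset, force_onset)` are
#' movement, and `[force_onset, force_onset + force_win_s)` are force; all
#' other bins are unlabeled. The force window is truncated (default 0.5 s) to
#' keep class sizes comparable.
#'
#' @param trials a `trial_table` from [detect_onsets()] (or the ground-truth
#'   onset table; needs cue/movement/force onset columns).
#' @param bin_times feature-bin center times, seconds.
#' @param force_win_s force-mode window length, seconds.
#' @return A `mode_labels` list: `label` (factor premovement/movement/force/
#'   unlabeled per bin), `trial` (integer or NA per bin), `bin_times`.
#' @export
label_modes <- function(trials, bin_times, force_win_s = 0.5) {
  tr <- trials[if ("valid" %in% names(trials)) trials$valid else TRUE, ]
  lab <- rep("unlabeled", length(bin_times))
  trial_of <- rep(NA_integer_, length(bin_times))
  if (nrow(tr) > 1L) {
    win_end <- tr$force_onset_s + force_win_s
    stop_if(any(win_end[-nrow(tr)] > tr$cue_time_s[-1] + 1e-9),
            "overlapping trials: a force window extends past the next cue")
  }
  for (i in seq_len(nrow(tr))) {
    pm <- bin_times >= tr$cue_time_s[i] & bin_times < tr$movement_onset_s[i]
    mv <- bin_times >= tr$movement_onset_s[i] & bin_times < tr$force_onset_s[i]
    fo <- bin_times >= tr$force_onset_s[i] &
      bin_times < tr$force_onset_s[i] + force_win_s
    lab[pm] <- "premovement"; lab[mv] <- "movement"; lab[fo] <- "force"
    trial_of[pm | mv | fo] <- tr$trial[i]
  }
  structure(list(
    label = factor(lab, levels = c("premovement", "movement", "force", "unlabeled")),
    trial = trial_of,
    bin_times = bin_times,
    force_win_s = force_win_s
  ), class = "mode_labels")
}
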