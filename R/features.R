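#' Default analysis bands
#'
#' Broadband low-frequency (8-55 Hz, typically suppressed during movement) and
#' broadband high-frequency (70-150 Hz, typically elevated with local cortical
#' activation).
#' @return A list of band definitions, each with `name`, `lo_hz`, `hi_hz`.
#' @export
default_bands <- function() {
  list(band_definition("low", 8, 55), band_definition("high", 70, 150))
}

#' Define a frequency band
#' @param name band label.
#' @param lo_hz,hi_hz band edges in Hz, `0 < lo_hz < hi_hz`.
#' @return A `band_definition` list.
#' @export
band_definition <- function(name, lo_hz, hi_hz) {
  stop_if(!(lo_hz > 0 && hi_hz > lo_hz), "band edges must satisfy 0 < lo < hi")
  structure(list(name = name, lo_hz = lo_hz, hi_hz = hi_hz),
            class = "band_definition")
}

#' Band-power feature extraction (Hanning / FFT / log-normalization)
#'
#' Slides a Hanning-tapered window along each channel, Fourier-transforms each
#' segment, takes log power, normalizes per channel and frequency bin by
#' subtracting the log of the mean power over the entire record, and averages
#' the normalized values over the frequency bins whose centers fall inside each
#' band (edges inclusive). With the defaults (256-ms window, 25-ms hop at
#' 2 kHz) the frequency resolution is fs/512 = 3.90625 Hz and consecutive bins
#' overlap by 231 ms.
#'
#' @param recording an `ecog_recording` (or any list with `signal` matrix
#'   samples x channels and `fs_hz`).
#' @param bands list of [band_definition()]s; defaults to [default_bands()].
#' @param window_s analysis window length, seconds (default 0.256).
#' @param step_s hop between window starts, seconds (default 0.025).
#' @param eps additive guard before taking logs of power.
#' @return A `feature_tensor`: `values` (bins x features, electrode-major then
#'   band), `bin_times` (window-center times, s), `window_s`, `step_s`,
#'   `feature_index` (tibble: column, channel, band), `fs_hz`, and the channel
#'   table carried over from the recording.
#' @export
compute_band_features <- function(recording, bands = default_bands(),
                                  window_s = 0.256, step_s = 0.025,
                                  eps = 1e-12) {
  sig <- recording$signal
  fs <- recording$fs_hz
  stop_if(is.null(sig) || is.null(fs), "recording must carry $signal and $fs_hz")
  win <- round(window_s * fs)
  hop <- round(step_s * fs)
  n_samp <- nrow(sig)
  n_ch <- ncol(sig)
  stop_if(n_samp < win, "recording shorter than one analysis window")
  n_bins <- (n_samp - win) %/% hop + 1L
  starts <- (seq_len(n_bins) - 1L) * hop
  freqs <- (0:(win %/% 2)) * fs / win
  for (b in bands) {
    stop_if(!any(freqs >= b$lo_hz & freqs <= b$hi_hz),
            "band '", b$name, "' (", b$lo_hz, "-", b$hi_hz,
            " Hz) contains no resolvable frequency bins at fs = ", fs, " Hz")
  }
  hann <- 0.5 - 0.5 * cos(2 * pi * (0:(win - 1L)) / (win - 1L))
  sel <- lapply(bands, function(b) which(freqs >= b$lo_hz & freqs <= b$hi_hz))
  idx <- outer(seq_len(win), starts, `+`)   # win x n_bins sample indices

  n_bands <- length(bands)
  values <- matrix(NA_real_, n_bins, n_ch * n_bands)
  for (ch in seq_len(n_ch)) {
    x <- sig[, ch]
    if (!all(is.finite(x))) {
      bad <- which(!is.finite(x))[1]
      stop("non-finite sample in channel ", ch, " at t = ",
           signif((bad - 1) / fs, 6), " s", call. = FALSE)
    }
    segs <- matrix(x[idx], win, n_bins) * hann
    P <- Mod(stats::mvfft(segs)[seq_along(freqs), , drop = FALSE])^2
    norm_log <- log(P + eps) - log(rowMeans(P) + eps)
    for (bi in seq_len(n_bands)) {
      values[, (ch - 1L) * n_bands + bi] <- colMeans(norm_log[sel[[bi]], , drop = FALSE])
    }
  }
  feature_index <- tibble::tibble(
    column = seq_len(n_ch * n_bands),
    channel = rep(seq_len(n_ch), each = n_bands),
    band = rep(vapply(bands, `[[`, "", "name"), times = n_ch)
  )
  structure(list(
    values = values,
    bin_times = (starts + win / 2) / fs,
    window_s = window_s, step_s = step_s,
    freq_resolution_hz = fs / win,
    feature_index = feature_index,
    fs_hz = fs,
    channels = recording$channels
  ), class = "feature_tensor")
}

#' Causal lagged design matrix for decoding
#'
#' Row `t` concatenates feature rows `t, t-1, ..., t-n_lags+1` (causal history
#' only), giving `M = n_features * n_lags` columns. Rows with incomplete
#' history are dropped and `bin_times` shortened to match.
#'
#' @param features a `feature_tensor`.
#' @param n_lags number of causal history bins (default 10).
#' @return A `lagged_design`: `values` (bins x M), `bin_times`, `n_lags`,
#'   `feature_index` of the underlying features.
#' @export
build_lagged_design <- function(features, n_lags = 10L) {
  stop_if(n_lags < 1L, "n_lags must be >= 1")
  v <- features$values
  stop_if(n_lags > nrow(v), "n_lags (", n_lags, ") exceeds number of bins (",
          nrow(v), ")")
  rows <- n_lags:nrow(v)
  blocks <- lapply(0:(n_lags - 1L), function(l) v[rows - l, , drop = FALSE])
  X <- do.call(cbind, blocks)
  colnames(X) <- paste0("f", rep(seq_len(ncol(v)), times = n_lags),
                        "_lag", rep(0:(n_lags - 1L), each = ncol(v)))
  structure(list(
    values = X,
    bin_times = features$bin_times[rows],
    n_lags = as.integer(n_lags),
    step_s = features$step_s,
    feature_index = features$feature_index
  ), class = "lagged_design")
}

#' Event-aligned intensity raster for one feature
#'
#' Windows a single feature around each event, z-scores it using the feature's
#' session-wide mean and SD (zero-variance features yield all-zero rows), and
#' orders rows by `sort_key`. Events whose window would leave the record are
#' excluded with a warning.
#'
#' @param features a `feature_tensor`.
#' @param feature column index of the feature to raster.
#' @param event_times event times in seconds (one per trial).
#' @param pre_s,post_s window extent before/after each event, seconds.
#' @param sort_key optional numeric vector (same length as `event_times`) used
#'   to order rows ascending, e.g. elapsed time between behavioral events.
#' @return Matrix trials x peri-event bins with attributes `rel_times_s`
#'   (bin-center times relative to the event) and `events` (kept indices in
#'   row order).
#' @export
event_aligned_raster <- function(features, feature, event_times,
                                 pre_s = 1, post_s = 1, sort_key = NULL) {
  stop_if(feature < 1L || feature > ncol(features$values), "bad feature column")
  step <- features$step_s
  n_pre <- round(pre_s / step)
  n_post <- round(post_s / step)
  rel <- (-n_pre):n_post
  x <- features$values[, feature]
  mu <- mean(x); sdev <- stats::sd(x)
  z <- if (sdev > 0) (x - mu) / sdev else rep(0, length(x))
  centers <- vapply(event_times, function(et) {
    which.min(abs(features$bin_times - et))
  }, integer(1))
  ok <- centers + min(rel) >= 1L & centers + max(rel) <= length(z) &
    abs(features$bin_times[centers] - event_times) <= step
  if (any(!ok)) {
    warning(sum(!ok), " event(s) too close to the record edge were excluded")
  }
  keep <- which(ok)
  if (!is.null(sort_key)) {
    stop_if(length(sort_key) != length(event_times),
            "sort_key must match event_times in length")
    keep <- keep[order(sort_key[keep])]
  }
  out <- t(vapply(keep, function(i) z[centers[i] + rel], numeric(length(rel))))
  attr(out, "rel_times_s") <- rel * step
  attr(out, "events") <- keep
  out
}

#' @export
print.feature_tensor <- function(x, ...) {
  cat("<feature_tensor> ", nrow(x$values), " bins x ", ncol(x$values),
      " features (", x$window_s * 1000, "-ms window, ", x$step_s * 1000,
      "-ms step, ", signif(x$freq_resolution_hz, 4), "-Hz resolution)\n",
      sep = "")
  invisible(x)
}
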