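#' Trial-averaged peri-event feature traces
#'
#' Convenience wrapper: averages peri-event windows (default aligned to force
#' onset, z-scored) across trials, giving one trace per feature — the input to
#' feature clustering.
#'
#' @param windows a `trial_windows` object.
#' @return Matrix features x peri-event bins, with the window's feature index
#'   and times as attributes.
#' @export
trial_average_features <- function(windows) {
  out <- t(apply(windows$values, c(2, 3), mean))
  attr(out, "feature_index") <- windows$feature_index
  attr(out, "rel_times_s") <- windows$rel_times_s
  out
}

#' Select well-modulated feature clusters by k-means
#'
#' Partitions trial-averaged feature traces into `k` clusters (k-means with
#' multiple restarts, squared-Euclidean distance over time bins), scores the
#' partition with silhouette values, and selects the two clusters with the
#' largest modulation depth (peak-to-trough of the cluster-mean trace). The
#' selected clusters are tagged low/high by the majority band of their
#' members — in practice, a well-modulated low-frequency cluster and a
#' well-modulated high-frequency cluster, leaving a poorly modulated
#' remainder.
#'
#' @param trial_avg matrix features x time (e.g. [trial_average_features()]);
#'   must carry a `feature_index` attribute with a `band` column, or pass
#'   `bands`.
#' @param k number of clusters (2-5; default 3).
#' @param seed seed for the k-means restarts.
#' @param bands optional character vector of band names per feature.
#' @param n_restarts k-means restarts.
#' @return A `feature_clustering` list: `cluster` (id per feature), `k`,
#'   `silhouette` (per feature), `mean_silhouette`, `selected` (two cluster
#'   ids, ordered by modulation depth), `tags` (band tag per selected
#'   cluster), `modulation_depth`, `centers`.
#' @export
select_feature_clusters <- function(trial_avg, k = 3L, seed = 1L,
                                    bands = NULL, n_restarts = 20L) {
  stop_if(k < 2L || k > 5L, "k must be between 2 and 5")
  stop_if(nrow(trial_avg) < k, "need at least k features")
  if (is.null(bands)) {
    fi <- attr(trial_avg, "feature_index")
    stop_if(is.null(fi), "supply `bands` or a feature_index attribute")
    bands <- fi$band
  }
  set.seed(seed)
  km <- stats::kmeans(trial_avg, centers = k, nstart = n_restarts,
                      iter.max = 100L)
  sil <- cluster::silhouette(km$cluster, stats::dist(trial_avg))
  sil_w <- if (is.matrix(sil)) sil[, "sil_width"] else rep(NA_real_, nrow(trial_avg))
  depth <- apply(km$centers, 1, function(tr) max(tr) - min(tr))
  selected <- order(depth, decreasing = TRUE)[1:2]
  tags <- vapply(selected, function(cl) {
    names(sort(table(bands[km$cluster == cl]), decreasing = TRUE))[1]
  }, character(1))
  structure(list(
    cluster = km$cluster, k = as.integer(k),
    silhouette = sil_w, mean_silhouette = mean(sil_w),
    selected = selected, tags = tags,
    modulation_depth = depth, centers = km$centers,
    bands = bands
  ), class = "feature_clustering")
}

#' Angle between a neural vector and a reference vector
#'
#' `acos` of the normalized inner product, in degrees (0-180). Returns `NA`
#' when either norm is at or below `eps`.
#'
#' @param m_t,m_ref numeric vectors of equal dimension.
#' @param eps norm guard (default 1e-9).
#' @return Angle in degrees, or `NA_real_`.
#' @export
neural_vector_angle <- function(m_t, m_ref, eps = 1e-9) {
  stop_if(length(m_t) != length(m_ref), "dimension mismatch")
  n1 <- sqrt(sum(m_t^2)); n2 <- sqrt(sum(m_ref^2))
  if (n1 <= eps || n2 <= eps) return(NA_real_)
  acos(clamp(sum(m_t * m_ref) / (n1 * n2), -1, 1)) * 180 / pi
}

#' Neural vector angle time course per trial
#'
#' For each selected feature cluster: forms the neural vector `m(t)` from the
#' cluster's features in each peri-event trial window, smooths it with a
#' centered moving average (default 5 bins = 125 ms at 25-ms resolution),
#' takes the per-trial reference vector as the mean of `m(t)` over the
#' `ref_s` (default 250 ms) before the trial's peak-force time, and computes
#' the angle per bin. Angles are in degrees, so they can be pooled across
#' trials and sessions.
#'
#' @param windows `trial_windows` aligned to force onset.
#' @param clustering a `feature_clustering` over the same features.
#' @param trials trial table carrying `force_onset_s` and `peak_force_time_s`
#'   for the windowed trials.
#' @param smooth_bins centered moving-average width in bins.
#' @param ref_s reference-window length before peak force, seconds.
#' @return An `nva_result`: tibble `angles` (trial, band, rel_time_s, theta)
#'   and the per-trial reference window used.
#' @export
nva_time_course <- function(windows, clustering, trials,
                            smooth_bins = 5L, ref_s = 0.25) {
  stop_if(length(clustering$cluster) != dim(windows$values)[3],
          "clustering does not match the window's feature count")
  tr <- trials[match(windows$trials, trials$trial), ]
  stop_if(!all(c("force_onset_s", "peak_force_time_s") %in% names(tr)),
          "trials must carry force_onset_s and peak_force_time_s")
  rel <- windows$rel_times_s
  step <- windows$step_s
  rows <- list()
  skipped <- 0L
  for (ci in seq_along(clustering$selected)) {
    cl <- clustering$selected[ci]
    members <- which(clustering$cluster == cl)
    tag <- clustering$tags[ci]
    for (i in seq_len(dim(windows$values)[1])) {
      rel_peak <- tr$peak_force_time_s[i] - tr$force_onset_s[i]
      ref_bins <- which(rel >= rel_peak - ref_s & rel < rel_peak)
      if (length(ref_bins) == 0L) { skipped <- skipped + 1L; next }
      M <- windows$values[i, , members, drop = FALSE]
      M <- matrix(M, length(rel), length(members))
      Ms <- apply(M, 2, moving_average, width = smooth_bins)
      m_ref <- colMeans(Ms[ref_bins, , drop = FALSE], na.rm = TRUE)
      theta <- vapply(seq_along(rel), function(b) {
        m <- Ms[b, ]
        if (any(!is.finite(m))) return(NA_real_)
        neural_vector_angle(m, m_ref)
      }, numeric(1))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        trial = tr$trial[i], band = tag, rel_time_s = rel, theta = theta
      )
    }
  }
  if (skipped > 0L) {
    warning(skipped, " trial/cluster combination(s) skipped: reference window ",
            "outside the peri-event window")
  }
  structure(list(
    angles = do.call(rbind, rows),
    smooth_bins = as.integer(smooth_bins),
    smooth_span_s = smooth_bins * step,
    ref_s = ref_s
  ), class = "nva_result")
}

#' Test NVA differences across behavioral modes
#'
#' Labels every angle sample with its trial's behavioral mode (premovement,
#' movement, or force, from the trial's onset times), runs a Kruskal-Wallis
#' test of unequal medians across modes, and follows with pairwise Tukey HSD
#' comparisons on the rank-transformed angles.
#'
#' @param result an `nva_result`.
#' @param trials trial table with cue/movement/force onset times.
#' @param band which band's angles to test (default `"high"`).
#' @param force_win_s force-mode window length, seconds.
#' @return List: `p_value`, `statistic`, `df` (Kruskal-Wallis), `posthoc`
#'   (data frame of pairwise rank comparisons), `n_per_mode`, `flagged`
#'   (TRUE when fewer than three modes had enough samples).
#' @export
compare_modes_nva <- function(result, trials, band = "high",
                              force_win_s = 0.5) {
  a <- result$angles[result$angles$band == band & is.finite(result$angles$theta), ]
  stop_if(nrow(a) == 0L, "no angle samples for band '", band, "'")
  tr <- trials[match(a$trial, trials$trial), ]
  abs_time <- tr$force_onset_s + a$rel_time_s
  mode <- rep(NA_character_, nrow(a))
  mode[abs_time >= tr$cue_time_s & abs_time < tr$movement_onset_s] <- "premovement"
  mode[abs_time >= tr$movement_onset_s & abs_time < tr$force_onset_s] <- "movement"
  mode[abs_time >= tr$force_onset_s &
         abs_time < tr$force_onset_s + force_win_s] <- "force"
  keep <- !is.na(mode)
  theta <- a$theta[keep]
  mode <- factor(mode[keep], levels = c("premovement", "movement", "force"))
  counts <- table(mode)
  usable <- names(counts)[counts >= 5L]
  flagged <- length(usable) < 3L
  stop_if(length(usable) < 2L, "need at least two modes with >= 5 samples")
  sel <- mode %in% usable
  theta <- theta[sel]; mode <- droplevels(mode[sel])
  kw <- stats::kruskal.test(theta, mode)
  rk <- rank(theta)
  hsd <- stats::TukeyHSD(stats::aov(rk ~ mode))$mode
  list(
    p_value = unname(kw$p.value),
    statistic = unname(kw$statistic),
    df = unname(kw$parameter),
    posthoc = as.data.frame(hsd),
    n_per_mode = counts,
    flagged = flagged
  )
}
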