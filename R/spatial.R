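#' Per-electrode decoding maps across cross-validation folds
#'
#' Decodes the target from each electrode alone (its two band features with
#' causal lag history) using the cross-validated Wiener cascade, and records
#' every electrode's test-fold FVAF. The per-fold spatial distribution of FVAF
#' over the grid is a decoding "map".
#'
#' @param features a `feature_tensor` (must carry the channel table).
#' @param target numeric target trace aligned to the lagged bin times (use
#'   [align_target()] on the lagged design's `bin_times`).
#' @param mode map tag, `"movement"` or `"force"`.
#' @param n_folds folds per map (default 10).
#' @param n_lags causal history bins per electrode design.
#' @param lambda_grid ridge penalties passed to [crossval_decode()].
#' @return A tibble of class `decoding_maps`: channel, row, col, x_mm, y_mm,
#'   fold, mode, fvaf. Electrodes whose decoder fails are recorded as NA with
#'   a warning.
#' @export
single_electrode_maps <- function(features, target, mode = "movement",
                                  n_folds = 10L, n_lags = 10L,
                                  lambda_grid = 10^seq(-4, 8, length.out = 13)) {
  stop_if(is.null(features$channels), "feature tensor carries no channel table")
  chans <- features$channels
  out <- lapply(chans$channel, function(ch) {
    cols <- features$feature_index$column[features$feature_index$channel == ch]
    sub <- features
    sub$values <- features$values[, cols, drop = FALSE]
    sub$feature_index <- features$feature_index[cols, ]
    fv <- tryCatch({
      des <- build_lagged_design(sub, n_lags)
      cv <- crossval_decode(des, target, n_folds = n_folds,
                            lambda_grid = lambda_grid)
      cv$folds$fvaf
    }, error = function(e) {
      warning("electrode ", ch, " marked missing: ", conditionMessage(e))
      rep(NA_real_, n_folds)
    })
    crow <- chans[chans$channel == ch, ]
    tibble::tibble(channel = ch, row = crow$row, col = crow$col,
                   x_mm = crow$x_mm, y_mm = crow$y_mm,
                   fold = seq_len(n_folds), mode = mode, fvaf = fv)
  })
  res <- do.call(rbind, out)
  class(res) <- c("decoding_maps", class(res))
  res
}

# split a decoding_maps tibble into per-fold single maps (ordered by row, col)
split_maps_by_fold <- function(maps) {
  maps <- maps[order(maps$fold, maps$row, maps$col), ]
  lapply(split(seq_len(nrow(maps)), maps$fold), function(i) maps[i, ])
}

#' Displacement between the peaks of two decoding maps
#'
#' Euclidean distance in millimetres between the argmax electrodes of two
#' single-fold maps on the same grid. Ties are broken by row-major first
#' occurrence.
#'
#' @param map_a,map_b single-fold maps: data frames with `x_mm`, `y_mm`,
#'   `row`, `col`, `fvaf` (one row per electrode).
#' @return Peak displacement in mm.
#' @export
peak_displacement <- function(map_a, map_b) {
  pk <- function(m) {
    m <- m[order(m$row, m$col), ]
    v <- m$fvaf
    stop_if(all(is.na(v)), "map has no non-missing electrodes")
    i <- which(v == max(v, na.rm = TRUE))[1]
    c(m$x_mm[i], m$y_mm[i])
  }
  a <- pk(map_a); b <- pk(map_b)
  sqrt(sum((a - b)^2))
}

#' Normalized Euclidean distance between two decoding maps
#'
#' Treats each map as an image with FVAF pixel intensities clipped to
#' `[0, 1]`, and returns the Euclidean distance between the two intensity
#' vectors scaled by the maximum possible distance (`sqrt(n_electrodes)`), so
#' the result lies in `[0, 1]`.
#'
#' @param map_a,map_b single-fold maps over the same electrode set.
#' @return Distance `D` in `[0, 1]`.
#' @export
map_distance <- function(map_a, map_b) {
  a <- map_a[order(map_a$row, map_a$col), ]
  b <- map_b[order(map_b$row, map_b$col), ]
  stop_if(nrow(a) != nrow(b) || any(a$channel != b$channel),
          "maps cover different electrode sets")
  va <- clamp(a$fvaf, 0, 1)
  vb <- clamp(b$fvaf, 0, 1)
  ok <- !is.na(va) & !is.na(vb)
  stop_if(!any(ok), "no shared non-missing electrodes")
  sqrt(sum((va[ok] - vb[ok])^2)) / sqrt(sum(ok))
}

#' Compare between-mode and within-mode decoding-map distances
#'
#' Computes `D_inter` (movement-fold vs force-fold map distances over all fold
#' pairs), `D_intra` for each mode (within-mode fold pairs, the control that
#' varies only with time), per-fold peak displacements, and a one-tailed
#' Wilcoxon signed-rank test of `D_inter > D_intra`. For the paired test, each
#' unordered fold pair (i, j) contributes the symmetrized cross-mode distance
#' and, as its control, the mean of the two within-mode distances for the same
#' fold pair.
#'
#' @param maps_mvt,maps_force `decoding_maps` tibbles for the two modes.
#' @param bonferroni multiplicity factor applied to the p-value (number of
#'   sessions tested in a batch).
#' @param test_pairing fold pairs entering the signed-rank test: `"disjoint"`
#'   (default; each fold appears in exactly one pair, keeping the test's
#'   differences independent and its size at the nominal level) or `"all"`
#'   (every unordered fold pair; more pairs but they share folds, which makes
#'   the signed-rank test anticonservative). The reported distance summaries
#'   always use all pairs.
#' @return A `map_comparison` list: distance vectors, per-fold displacements
#'   (mm), medians, and `test` (V statistic, raw and adjusted p).
#' @export
compare_inter_intra <- function(maps_mvt, maps_force, bonferroni = 1L,
                                test_pairing = c("disjoint", "all")) {
  test_pairing <- match.arg(test_pairing)
  ma <- split_maps_by_fold(maps_mvt)
  mf <- split_maps_by_fold(maps_force)
  folds <- intersect(names(ma), names(mf))
  stop_if(length(folds) < 3L, "need at least 3 folds per mode")
  ma <- ma[folds]; mf <- mf[folds]
  nf <- length(folds)

  d_inter <- matrix(NA_real_, nf, nf)
  for (i in seq_len(nf)) for (j in seq_len(nf)) {
    d_inter[i, j] <- map_distance(ma[[i]], mf[[j]])
  }
  pair_idx <- which(upper.tri(matrix(0, nf, nf)), arr.ind = TRUE)
  d_intra_m <- apply(pair_idx, 1, function(p) map_distance(ma[[p[1]]], ma[[p[2]]]))
  d_intra_f <- apply(pair_idx, 1, function(p) map_distance(mf[[p[1]]], mf[[p[2]]]))

  if (test_pairing == "disjoint") {
    ii <- seq(1L, nf - 1L, by = 2L)
    test_pairs <- cbind(ii, ii + 1L)
  } else {
    test_pairs <- pair_idx
  }
  inter_sym <- apply(test_pairs, 1, function(p) {
    (d_inter[p[1], p[2]] + d_inter[p[2], p[1]]) / 2
  })
  intra_ctrl <- apply(test_pairs, 1, function(p) {
    (map_distance(ma[[p[1]]], ma[[p[2]]]) +
       map_distance(mf[[p[1]]], mf[[p[2]]])) / 2
  })
  if (all(abs(inter_sym - intra_ctrl) < 1e-12)) {
    # degenerate case (e.g. identical map sets): no evidence either way
    test <- list(statistic = 0, p.value = 1)
  } else {
    test <- suppressWarnings(
      stats::wilcox.test(inter_sym, intra_ctrl, paired = TRUE,
                         alternative = "greater"))
  }
  displacement <- vapply(seq_len(nf), function(i) {
    peak_displacement(ma[[i]], mf[[i]])
  }, numeric(1))

  structure(list(
    d_inter = as.numeric(d_inter),
    d_intra_mvt = d_intra_m,
    d_intra_force = d_intra_f,
    d_inter_paired = inter_sym,
    d_intra_paired = intra_ctrl,
    displacement_mm = displacement,
    median_d_inter = stats::median(as.numeric(d_inter)),
    median_d_intra = stats::median(c(d_intra_m, d_intra_f)),
    test = list(statistic = unname(test$statistic),
                p_value = unname(test$p.value),
                p_adjusted = min(1, unname(test$p.value) * bonferroni))
  ), class = "map_comparison")
}

#' @export
print.map_comparison <- function(x, ...) {
  cat("<map_comparison> median D_inter ", signif(x$median_d_inter, 3),
      " vs D_intra ", signif(x$median_d_intra, 3),
      "; displacement ", signif(mean(x$displacement_mm), 3), " +/- ",
      signif(stats::sd(x$displacement_mm), 3), " mm; p = ",
      signif(x$test$p_adjusted, 3), " (one-tailed signed-rank)\n", sep = "")
  invisible(x)
}
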