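#' Fractional variance accounted for
#'
#' `1 - SSE/SST`: 1 for a perfect prediction, 0 for predicting the mean of the
#' actual trace, negative (uncapped) for worse-than-mean predictions.
#'
#' @param predicted,actual numeric vectors of equal length (>= 2).
#' @return A single number in `(-Inf, 1]`.
#' @export
fvaf <- function(predicted, actual) {
  stop_if(length(predicted) != length(actual), "length mismatch")
  stop_if(length(actual) < 2L, "need at least 2 samples")
  stop_if(!all(is.finite(predicted)) || !all(is.finite(actual)),
          "non-finite values")
  sst <- sum((actual - mean(actual))^2)
  stop_if(sst == 0, "actual trace is constant; FVAF undefined")
  1 - sum((actual - predicted)^2) / sst
}

# Ridge solutions for a whole lambda path from one SVD.
# Returns list(weights = M x n_lambda, intercepts, plus cached pieces).
ridge_path <- function(x, y, lambdas) {
  cm <- colMeans(x)
  my <- mean(y)
  xc <- sweep(x, 2, cm)
  s <- svd(xc)
  uty <- crossprod(s$u, y - my)
  tiny <- s$d < max(s$d, 1e-300) * 1e-12   # pseudo-inverse behavior at lambda = 0
  W <- vapply(lambdas, function(l) {
    shrink <- s$d / (s$d^2 + l)
    if (l == 0) shrink[tiny] <- 0
    s$v %*% (shrink * uty)
  }, numeric(ncol(x)))
  W <- matrix(W, ncol = length(lambdas))
  b <- my - drop(crossprod(cm, W))
  list(weights = W, intercepts = b, col_means = cm, y_mean = my)
}

fit_cubic_stage <- function(u, y) {
  if (stats::sd(u) < 1e-10) return(c(mean(y), 0, 0, 0))
  X <- cbind(1, u, u^2, u^3)
  fit <- stats::lm.fit(X, y)
  co <- fit$coefficients
  co[!is.finite(co)] <- 0
  co
}

#' Fit a ridge-regularized Wiener cascade
#'
#' Linear stage: ridge regression of the target on the lagged feature design.
#' Static nonlinearity: a third-order polynomial fit by least squares to the
#' target as a function of the linear stage's training output. Predictions are
#' `poly(linear(x))`.
#'
#' @param design a `lagged_design` or a plain numeric matrix (rows aligned to
#'   target samples at bin times).
#' @param target numeric target trace, one value per design row.
#' @param ridge_lambda ridge penalty (0 = ordinary least squares).
#' @return A `wiener_cascade` model: `weights`, `intercept`, `poly_coeffs`
#'   (length 4, constant first), `ridge_lambda`.
#' @export
fit_wiener_cascade <- function(design, target, ridge_lambda = 0) {
  x <- if (is.list(design)) design$values else design
  stop_if(nrow(x) != length(target), "design rows must match target length")
  stop_if(nrow(x) < 2L, "need at least 2 rows")
  stop_if(!all(is.finite(target)), "non-finite target values")
  rp <- ridge_path(x, target, ridge_lambda)
  w <- rp$weights[, 1]
  b <- rp$intercepts[1]
  u <- drop(x %*% w) + b
  structure(list(
    weights = w, intercept = b,
    poly_coeffs = fit_cubic_stage(u, target),
    ridge_lambda = ridge_lambda
  ), class = "wiener_cascade")
}

#' Predict from a Wiener cascade
#' @param object a `wiener_cascade`.
#' @param newdata a `lagged_design` or matrix with the same columns as used in
#'   fitting.
#' @param ... unused.
#' @return Numeric predictions, one per row.
#' @export
predict.wiener_cascade <- function(object, newdata, ...) {
  x <- if (is.list(newdata)) newdata$values else newdata
  stop_if(ncol(x) != length(object$weights), "feature-count mismatch")
  u <- drop(x %*% object$weights) + object$intercept
  p <- object$poly_coeffs
  p[1] + p[2] * u + p[3] * u^2 + p[4] * u^3
}

contiguous_folds <- function(n, n_folds) {
  stop_if(n_folds < 3L, "need at least 3 folds (train/validation/test)")
  bounds <- floor(seq(0, n, length.out = n_folds + 1L))
  lapply(seq_len(n_folds), function(i) (bounds[i] + 1L):bounds[i + 1L])
}

#' Cross-validated Wiener-cascade decoding
#'
#' Contiguous time-block cross-validation (default 11 folds). For each test
#' fold, the next fold in sequence serves as the validation fold: the ridge
#' penalty is chosen from `lambda_grid` by validation-fold FVAF (ties broken
#' toward the smallest penalty), the cascade is fit on the remaining training
#' folds, and FVAF is reported on the test fold. All bins are used regardless
#' of behavioral mode.
#'
#' @param design a `lagged_design` or numeric matrix.
#' @param target numeric target trace aligned to the design rows.
#' @param n_folds number of folds (default 11: 9 train / 1 validation / 1 test).
#' @param lambda_grid candidate ridge penalties (default 13 log-spaced values,
#'   1e-4 to 1e8; the upper end admits an effectively constant model so the
#'   validation fold can fall back to a mean predictor for uninformative
#'   targets).
#' @param min_bins_per_fold guard on fold size.
#' @return A `cv_result`: tibble `folds` (fold, chosen lambda, test FVAF),
#'   the fitted per-fold `models`, `fold_bounds`, and `median`/`iqr` of
#'   test-fold FVAF.
#' @export
crossval_decode <- function(design, target, n_folds = 11L,
                            lambda_grid = 10^seq(-4, 8, length.out = 13),
                            min_bins_per_fold = 20L) {
  x <- if (is.list(design)) design$values else design
  stop_if(nrow(x) != length(target), "design rows must match target length")
  stop_if(nrow(x) < n_folds * min_bins_per_fold,
          "too few bins (", nrow(x), ") for ", n_folds, " folds of at least ",
          min_bins_per_fold)
  folds <- contiguous_folds(nrow(x), n_folds)
  lambda_grid <- sort(lambda_grid)
  res <- lapply(seq_len(n_folds), function(i) {
    val_fold <- i %% n_folds + 1L
    test_idx <- folds[[i]]
    val_idx <- folds[[val_fold]]
    train_idx <- setdiff(seq_len(nrow(x)), c(test_idx, val_idx))
    xtr <- x[train_idx, , drop = FALSE]
    ytr <- target[train_idx]
    rp <- ridge_path(xtr, ytr, lambda_grid)
    val_f <- vapply(seq_along(lambda_grid), function(j) {
      u_tr <- drop(xtr %*% rp$weights[, j]) + rp$intercepts[j]
      pc <- fit_cubic_stage(u_tr, ytr)
      u_v <- drop(x[val_idx, , drop = FALSE] %*% rp$weights[, j]) + rp$intercepts[j]
      pred <- pc[1] + pc[2] * u_v + pc[3] * u_v^2 + pc[4] * u_v^3
      fvaf(pred, target[val_idx])
    }, numeric(1))
    best <- which.max(val_f)          # grid sorted ascending -> lowest-lambda tie wins
    model <- structure(list(
      weights = rp$weights[, best], intercept = rp$intercepts[best],
      poly_coeffs = fit_cubic_stage(
        drop(xtr %*% rp$weights[, best]) + rp$intercepts[best], ytr),
      ridge_lambda = lambda_grid[best]
    ), class = "wiener_cascade")
    list(row = tibble::tibble(
      fold = i,
      ridge_lambda = lambda_grid[best],
      fvaf = fvaf(predict(model, x[test_idx, , drop = FALSE]), target[test_idx])
    ), model = model)
  })
  folds_tbl <- do.call(rbind, lapply(res, `[[`, "row"))
  structure(list(
    folds = folds_tbl,
    models = lapply(res, `[[`, "model"),
    fold_bounds = vapply(folds, range, integer(2)),
    median = stats::median(folds_tbl$fvaf),
    iqr = unname(diff(stats::quantile(folds_tbl$fvaf, c(0.25, 0.75))))
  ), class = "cv_result")
}

#' Sample a continuous trace at feature-bin times
#'
#' Helper aligning a 2-kHz behavioral trace to the decoder's 25-ms bins by
#' averaging the trace over each analysis window (matching the temporal
#' support of the spectral features).
#'
#' @param trace numeric trace sampled at `fs_hz`.
#' @param fs_hz sampling rate of the trace.
#' @param bin_times bin-center times from a `feature_tensor`/`lagged_design`.
#' @param window_s averaging window centered on each bin (default one bin).
#' @return Numeric vector, one value per bin.
#' @export
align_target <- function(trace, fs_hz, bin_times, window_s = 0.025) {
  half <- window_s / 2
  n <- length(trace)
  vapply(bin_times, function(bt) {
    i0 <- max(1L, floor((bt - half) * fs_hz) + 1L)
    i1 <- min(n, ceiling((bt + half) * fs_hz))
    mean(trace[i0:i1])
  }, numeric(1))
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", nrow(x$folds), " folds; test FVAF median ",
      signif(x$median, 3), " (IQR ", signif(x$iqr, 3), ")\n", sep = "")
  invisible(x)
}
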