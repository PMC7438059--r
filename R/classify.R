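#' Classify behavioral mode per time bin
#'
#' Three-class (premovement / movement / force) classification of individual
#' bins with contiguous-block cross-validation. Unlabeled bins are excluded.
#' Methods: radial-basis SVM (one-vs-one multiclass) or bagged decision trees
#' (100 trees, all features considered at every split).
#'
#' @param x numeric matrix, one row per bin (e.g. a lagged design restricted
#'   to labeled bins).
#' @param labels factor (or `mode_labels` object) with one label per row of
#'   `x`; `"unlabeled"` entries are dropped.
#' @param method `"svm"`, `"bagged_trees"`, or `"majority"` (predicts the
#'   training-set majority class; useful for chance calibration).
#' @param n_folds cross-validation folds (default 5).
#' @param seed seed for the stochastic learners.
#' @return A `mode_classification` list: tibble `folds` (fold, accuracy),
#'   pooled `confusion` matrix, `accuracy_median`, `accuracy_iqr`,
#'   `pooled_accuracy` (correct bins / test bins over all folds), `method`.
#' @export
classify_modes <- function(x, labels, method = c("bagged_trees", "svm", "majority"),
                           n_folds = 5L, seed = 1L) {
  method <- match.arg(method)
  if (inherits(labels, "mode_labels")) labels <- labels$label
  labels <- factor(labels)
  stop_if(nrow(x) != length(labels), "rows of x must match labels")
  keep <- labels != "unlabeled" & !is.na(labels)
  x <- x[keep, , drop = FALSE]
  y <- droplevels(labels[keep])
  stop_if(nlevels(y) < 2L, "need at least two labeled classes")
  stop_if(nrow(x) < n_folds * 2L, "too few labeled bins for ", n_folds, " folds")
  folds <- contiguous_folds(nrow(x), n_folds)
  set.seed(seed)
  conf <- matrix(0L, nlevels(y), nlevels(y),
                 dimnames = list(truth = levels(y), predicted = levels(y)))
  acc <- numeric(n_folds)
  for (i in seq_len(n_folds)) {
    test_idx <- folds[[i]]
    train_idx <- setdiff(seq_len(nrow(x)), test_idx)
    ytr <- y[train_idx]
    if (any(table(ytr) == 0L)) {
      stop("class '", levels(y)[which(table(ytr) == 0L)[1]],
           "' absent from a training fold; record more trials",
           call. = FALSE)
    }
    pred <- switch(method,
      svm = {
        fit <- e1071::svm(x[train_idx, , drop = FALSE], ytr, kernel = "radial")
        stats::predict(fit, x[test_idx, , drop = FALSE])
      },
      bagged_trees = {
        fit <- randomForest::randomForest(x[train_idx, , drop = FALSE], ytr,
                                          ntree = 100L,
                                          mtry = ncol(x))
        stats::predict(fit, x[test_idx, , drop = FALSE])
      },
      majority = {
        maj <- names(sort(table(ytr), decreasing = TRUE))[1]
        factor(rep(maj, length(test_idx)), levels = levels(y))
      }
    )
    acc[i] <- mean(pred == y[test_idx])
    conf <- conf + table(truth = y[test_idx],
                         predicted = factor(pred, levels = levels(y)))
  }
  structure(list(
    folds = tibble::tibble(fold = seq_len(n_folds), accuracy = acc),
    confusion = conf,
    accuracy_median = stats::median(acc),
    accuracy_iqr = unname(diff(stats::quantile(acc, c(0.25, 0.75)))),
    pooled_accuracy = sum(diag(conf)) / sum(conf),
    method = method, n_folds = as.integer(n_folds)
  ), class = "mode_classification")
}

#' Chance-level accuracy distribution by label permutation
#'
#' Repeats the classification analysis with permuted labels. Because bins are
#' temporally autocorrelated, the default permutes labels in whole-trial
#' blocks (the label runs of each trial are reordered across the record);
#' `unit = "bin"` permutes individual bin labels instead. Because class sizes
#' are not equal, the resulting chance level is not necessarily 1/3.
#'
#' @param x feature matrix, one row per bin.
#' @param labels factor per row (or `mode_labels`).
#' @param trial optional integer trial id per row, required for
#'   `unit = "trial"`.
#' @param n_shuffles number of permutations (>= 2; 1000 reproduces the full
#'   procedure, 200 is the desk default).
#' @param method classifier passed to [classify_modes()] (default
#'   `"majority"`, which isolates the class-prior contribution and keeps the
#'   permutation loop fast; pass the real classifier to reproduce the full
#'   procedure).
#' @param n_folds folds per permutation.
#' @param seed seed controlling the permutations.
#' @param unit permutation granularity: `"trial"` (default) or `"bin"`.
#' @return Numeric vector of pooled accuracies, one per shuffle, with class
#'   `chance_distribution`.
#' @export
chance_level <- function(x, labels, trial = NULL, n_shuffles = 200L,
                         method = "majority", n_folds = 5L, seed = 1L,
                         unit = c("trial", "bin")) {
  unit <- match.arg(unit)
  if (inherits(labels, "mode_labels")) {
    if (is.null(trial)) trial <- labels$trial
    labels <- labels$label
  }
  labels <- factor(labels)
  stop_if(n_shuffles < 2L, "n_shuffles must be >= 2")
  keep <- labels != "unlabeled" & !is.na(labels)
  x <- x[keep, , drop = FALSE]
  y <- droplevels(labels[keep])
  if (!is.null(trial)) trial <- trial[keep]
  if (unit == "trial") {
    stop_if(is.null(trial), "trial ids required for trial-level shuffling")
  }
  set.seed(seed)
  vapply(seq_len(n_shuffles), function(s) {
    y_perm <- if (unit == "bin") {
      sample(y)
    } else {
      # permute whole-trial label blocks across the (time-ordered) record
      blocks <- split(as.character(y), trial)
      perm <- unlist(blocks[sample(length(blocks))], use.names = FALSE)
      factor(perm[seq_along(y)], levels = levels(y))
    }
    res <- classify_modes(x, y_perm, method = method, n_folds = n_folds,
                          seed = seed + s)
    res$pooled_accuracy
  }, numeric(1)) -> out
  class(out) <- "chance_distribution"
  out
}

#' @export
print.mode_classification <- function(x, ...) {
  cat("<mode_classification> ", x$method, ", ", x$n_folds,
      " folds; accuracy median ", signif(x$accuracy_median, 3),
      " (IQR ", signif(x$accuracy_iqr, 3), ")\n", sep = "")
  invisible(x)
}

#' Compare classification accuracy between two input conditions
#'
#' Kruskal-Wallis test on the per-fold accuracies of two classification runs
#' (e.g. raw features vs denoised features) computed over the same folds and
#' labels.
#'
#' @param result_a,result_b `mode_classification` results with matching fold
#'   counts (> 1).
#' @return List: `p_value`, `statistic`, per-condition medians.
#' @export
compare_inputs <- function(result_a, result_b) {
  stop_if(result_a$n_folds != result_b$n_folds, "mismatched fold counts")
  stop_if(result_a$n_folds < 2L, "need more than one fold")
  acc <- c(result_a$folds$accuracy, result_b$folds$accuracy)
  grp <- factor(rep(c("a", "b"), each = result_a$n_folds))
  if (stats::sd(acc) == 0) {
    # identical accuracies in both arms: no evidence of a difference
    kw <- list(p.value = 1, statistic = 0)
  } else {
    kw <- stats::kruskal.test(acc, grp)
  }
  list(p_value = unname(kw$p.value), statistic = unname(kw$statistic),
       median_a = result_a$accuracy_median, median_b = result_b$accuracy_median)
}
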