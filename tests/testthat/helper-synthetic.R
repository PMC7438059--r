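# Shared fixtures, built in code at test time.

# small, fast session used by several unit tests (cached per test run)
tiny_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_session(sim_config(
        n_trials = 10L, n_rows = 4L, n_cols = 4L, snr = 6, seed = 42L))
    }
    cache
  }
})

tiny_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- compute_band_features(tiny_session()$recording)
    cache
  }
})

# ground-truth onset table in the shape label_modes()/nva expect
truth_trials <- function(session) {
  tt <- session$truth$true_onsets
  tt$valid <- TRUE
  tt
}

# autonomous linear-dynamical-system benchmark for the latent model:
# z_{t+1} = A z_t (slow damped rotation), x_t = C'z_t + noise, z-scored
gen_lds <- function(seed, n_trials = 60L, n_time = 50L, n_features = 40L,
                    latent_dim = 3L, noise_sd = 0.5) {
  set.seed(seed)
  th <- 2 * pi * 0.04
  A <- diag(latent_dim) * 0.98
  if (latent_dim >= 2L) {
    A[1:2, 1:2] <- 0.98 * matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
  }
  C <- matrix(rnorm(latent_dim * n_features), latent_dim, n_features)
  Z <- array(0, c(n_trials, n_time, latent_dim))
  X <- array(0, c(n_trials, n_time, n_features))
  for (n in seq_len(n_trials)) {
    z <- rnorm(latent_dim)
    for (t in seq_len(n_time)) {
      z <- drop(A %*% z)
      Z[n, t, ] <- z
      X[n, t, ] <- drop(z %*% C) + rnorm(n_features, sd = noise_sd)
    }
  }
  flat <- scale(matrix(aperm(X, c(2, 1, 3)), n_trials * n_time, n_features))
  list(X = aperm(array(flat, c(n_time, n_trials, n_features)),
                 c(2, 1, 3)),
       Z = Z)
}

flatten3 <- function(a) ecogrip:::flatten_windows(a)$x

# single-fold decoding map from a vector of per-electrode values on a grid
map_from_values <- function(values, n_rows, n_cols, pitch = 4, fold = 1L,
                            mode = "movement") {
  g <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  tibble::tibble(channel = seq_along(values), row = g$row, col = g$col,
                 x_mm = (g$col - 1) * pitch, y_mm = (g$row - 1) * pitch,
                 fold = fold, mode = mode, fvaf = values)
}

# stack one per-fold value matrix (electrodes x folds) into a decoding_maps tibble
maps_from_matrix <- function(m, n_rows, n_cols, pitch = 4, mode = "movement") {
  do.call(rbind, lapply(seq_len(ncol(m)), function(f) {
    map_from_values(m[, f], n_rows, n_cols, pitch, fold = f, mode = mode)
  }))
}

# separable three-class construction: disjoint feature means, tiny noise,
# organized in trial-like blocks (with jittered mode durations, as in the
# task) so contiguous folds see every class and trial label blocks differ
make_separable <- function(seed, n_trials = 20L, bins_per_mode = 6L,
                           n_features = 8L, noise = 0.01) {
  set.seed(seed)
  centers <- matrix(c(0, 4, 8), 3L, n_features)
  # draw the block-length structure first so two calls with the same seed but
  # different noise levels produce identically shaped data
  nb <- matrix(pmax(2L, bins_per_mode +
                      sample(-2:2, n_trials * 3L, replace = TRUE)),
               n_trials, 3L)
  lab <- character(0); x <- NULL; trial <- integer(0)
  for (i in seq_len(n_trials)) {
    for (m in 1:3) {
      x <- rbind(x, matrix(centers[m, ], nb[i, m], n_features, byrow = TRUE) +
                   matrix(rnorm(nb[i, m] * n_features, sd = noise), nb[i, m]))
      lab <- c(lab, rep(c("premovement", "movement", "force")[m], nb[i, m]))
      trial <- c(trial, rep(i, nb[i, m]))
    }
  }
  list(x = x, labels = factor(lab,
                              levels = c("premovement", "movement", "force")),
       trial = trial)
}

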