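#' Extract peri-event trial windows of z-scored features
#'
#' Z-scores every feature over the whole session (mean 0, SD 1; zero-variance
#' features are left at 0), then cuts a fixed window around each alignment
#' time (default -1.5 s to +0.75 s, covering premovement through force when
#' aligned to force onset). Trials whose window leaves the record are dropped
#' with a warning.
#'
#' @param features a `feature_tensor`.
#' @param align_times per-trial alignment times, seconds (e.g. force onsets).
#' @param pre_s,post_s window extent before/after the event, seconds.
#' @param z_score z-score features over the session first (default TRUE).
#' @return A `trial_windows` list: `values` (trials x time x features array),
#'   `rel_times_s`, `trials` (kept indices), `feature_index`, `step_s`,
#'   z-scoring `center`/`scale`.
#' @export
peri_event_windows <- function(features, align_times, pre_s = 1.5,
                               post_s = 0.75, z_score = TRUE) {
  step <- features$step_s
  rel <- (-round(pre_s / step)):(round(post_s / step))
  x <- features$values
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (z_score) {
    x <- sweep(x, 2, ctr)
    nz <- scl > 0
    x[, nz] <- sweep(x[, nz, drop = FALSE], 2, scl[nz], `/`)
  }
  centers <- vapply(align_times, function(et) {
    which.min(abs(features$bin_times - et))
  }, integer(1))
  ok <- centers + min(rel) >= 1L & centers + max(rel) <= nrow(x)
  if (any(!ok)) warning(sum(!ok), " trial(s) outside the record were dropped")
  keep <- which(ok)
  stop_if(length(keep) == 0L, "no trial windows fit inside the record")
  vals <- array(NA_real_, c(length(keep), length(rel), ncol(x)))
  for (i in seq_along(keep)) {
    vals[i, , ] <- x[centers[keep[i]] + rel, , drop = FALSE]
  }
  structure(list(
    values = vals, rel_times_s = rel * step, trials = keep,
    feature_index = features$feature_index, step_s = step,
    center = ctr, scale = scl, z_scored = z_score
  ), class = "trial_windows")
}

#' Restrict trial windows to one band's features
#' @param windows a `trial_windows` object.
#' @param band band name to keep (e.g. `"low"` or `"high"`).
#' @return A `trial_windows` over the selected feature columns.
#' @export
subset_windows <- function(windows, band) {
  cols <- which(windows$feature_index$band == band)
  stop_if(length(cols) == 0L, "no features in band '", band, "'")
  out <- windows
  out$values <- windows$values[, , cols, drop = FALSE]
  out$feature_index <- windows$feature_index[cols, ]
  out
}

# ---- Gaussian sequential autoencoder internals --------------------------------
# Parameters are plain matrices; forward/backward are hand-derived BPTT.
# States are row-major: one row per trial.

glfads_init <- function(n_features, enc_size, gen_size, n_factors, sigma_floor) {
  rn <- function(nr, nc, fan) matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(fan)), nr, nc)
  ortho <- function(n) qr.Q(qr(matrix(stats::rnorm(n * n), n)))
  list(
    We = rn(n_features, enc_size, n_features),
    Ue = 0.9 * ortho(enc_size), be = rep(0, enc_size),
    Web = rn(n_features, enc_size, n_features),
    Ueb = 0.9 * ortho(enc_size), beb = rep(0, enc_size),
    Wm = rn(2L * enc_size, gen_size, 2L * enc_size), bm = rep(0, gen_size),
    Wv = rn(2L * enc_size, gen_size, 2L * enc_size), bv = rep(-2, gen_size),
    Ug = 0.95 * ortho(gen_size), bg = rep(0, gen_size),
    Wf = rn(gen_size, n_factors, gen_size),
    W1 = rn(n_factors, n_features, n_factors), b1 = rep(0, n_features),
    W2 = rn(n_factors, n_features, n_factors), b2 = rep(0, n_features)
  )
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

# forward pass; X is a list over time of N x F matrices; eps N x G (or NULL
# for the posterior mean). Returns loss pieces and, if keep, all activations.
glfads_forward <- function(p, X, eps, beta, sigma_floor, keep = FALSE) {
  T_len <- length(X)
  N <- nrow(X[[1]])
  He <- ncol(p$We); G <- ncol(p$Wm)
  h <- matrix(0, N, He)
  H <- if (keep) vector("list", T_len)
  for (t in seq_len(T_len)) {
    h <- tanh(X[[t]] %*% p$We + h %*% p$Ue +
                matrix(p$be, N, He, byrow = TRUE))
    if (keep) H[[t]] <- h
  }
  hb <- matrix(0, N, He)
  HB <- if (keep) vector("list", T_len)
  for (t in rev(seq_len(T_len))) {
    hb <- tanh(X[[t]] %*% p$Web + hb %*% p$Ueb +
                 matrix(p$beb, N, He, byrow = TRUE))
    if (keep) HB[[t]] <- hb
  }
  e <- cbind(h, hb)
  mu0 <- e %*% p$Wm + matrix(p$bm, N, G, byrow = TRUE)
  lv0 <- clamp(e %*% p$Wv + matrix(p$bv, N, G, byrow = TRUE), -8, 8)
  g <- if (is.null(eps)) mu0 else mu0 + exp(0.5 * lv0) * eps
  g0 <- g
  Gs <- vector("list", T_len)
  for (t in seq_len(T_len)) {
    g <- tanh(g %*% p$Ug + matrix(p$bg, N, G, byrow = TRUE))
    Gs[[t]] <- g
  }
  nll <- 0
  MU <- SIG <- FAC <- if (keep || is.null(eps)) vector("list", T_len)
  for (t in seq_len(T_len)) {
    f <- Gs[[t]] %*% p$Wf
    mu <- f %*% p$W1 + matrix(p$b1, N, ncol(p$W1), byrow = TRUE)
    sg <- sigma_floor + softplus(f %*% p$W2 +
                                   matrix(p$b2, N, ncol(p$W2), byrow = TRUE))
    nll <- nll + sum(0.5 * (log(2 * pi) + 2 * log(sg) + ((X[[t]] - mu) / sg)^2))
    if (keep || is.null(eps)) { MU[[t]] <- mu; SIG[[t]] <- sg; FAC[[t]] <- f }
  }
  kl <- sum(0.5 * (mu0^2 + exp(lv0) - lv0 - 1))
  scale <- 1 / (N * T_len * ncol(X[[1]]))
  list(loss = (nll + beta * kl) * scale, nll = nll * scale, kl = kl * scale,
       H = if (keep) H, HB = if (keep) HB, e = e, mu0 = mu0, lv0 = lv0,
       g0 = g0, Gs = Gs, MU = MU, SIG = SIG, FAC = FAC, scale = scale)
}

glfads_backward <- function(p, X, eps, beta, sigma_floor, fw) {
  T_len <- length(X); N <- nrow(X[[1]]); Fn <- ncol(X[[1]])
  He <- ncol(p$We); G <- ncol(p$Wm); K <- ncol(p$Wf)
  sc <- fw$scale
  gr <- lapply(p, function(m) m * 0)
  d_g <- matrix(0, N, G)       # running dL/dg_t
  # local emission gradients feed into each g_t
  d_g_local <- vector("list", T_len)
  for (t in seq_len(T_len)) {
    mu <- fw$MU[[t]]; sg <- fw$SIG[[t]]; f <- fw$FAC[[t]]
    d_mu <- (mu - X[[t]]) / sg^2 * sc
    d_sg <- (1 / sg - (X[[t]] - mu)^2 / sg^3) * sc
    pre <- f %*% p$W2 + matrix(p$b2, N, Fn, byrow = TRUE)
    d_pre <- d_sg * stats::plogis(pre)
    gr$W1 <- gr$W1 + crossprod(f, d_mu)
    gr$b1 <- gr$b1 + colSums(d_mu)
    gr$W2 <- gr$W2 + crossprod(f, d_pre)
    gr$b2 <- gr$b2 + colSums(d_pre)
    d_f <- d_mu %*% t(p$W1) + d_pre %*% t(p$W2)
    gr$Wf <- gr$Wf + crossprod(fw$Gs[[t]], d_f)
    d_g_local[[t]] <- d_f %*% t(p$Wf)
  }
  for (t in rev(seq_len(T_len))) {
    d_g <- d_g + d_g_local[[t]]
    d_a <- d_g * (1 - fw$Gs[[t]]^2)
    g_prev <- if (t == 1L) fw$g0 else fw$Gs[[t - 1L]]
    gr$Ug <- gr$Ug + crossprod(g_prev, d_a)
    gr$bg <- gr$bg + colSums(d_a)
    d_g <- d_a %*% t(p$Ug)
  }
  d_g0 <- d_g
  d_mu0 <- d_g0 + beta * fw$mu0 * sc
  lv_free <- abs(fw$lv0) < 8 - 1e-12
  d_lv0 <- (0.5 * beta * (exp(fw$lv0) - 1) * sc)
  if (!is.null(eps)) d_lv0 <- d_lv0 + d_g0 * eps * 0.5 * exp(0.5 * fw$lv0)
  d_lv0 <- d_lv0 * lv_free
  gr$Wm <- crossprod(fw$e, d_mu0); gr$bm <- colSums(d_mu0)
  gr$Wv <- crossprod(fw$e, d_lv0); gr$bv <- colSums(d_lv0)
  d_e <- d_mu0 %*% t(p$Wm) + d_lv0 %*% t(p$Wv)
  d_h <- d_e[, seq_len(He), drop = FALSE]
  d_hb <- d_e[, He + seq_len(He), drop = FALSE]
  for (t in rev(seq_len(T_len))) {
    d_a <- d_h * (1 - fw$H[[t]]^2)
    h_prev <- if (t == 1L) matrix(0, N, He) else fw$H[[t - 1L]]
    gr$We <- gr$We + crossprod(X[[t]], d_a)
    gr$Ue <- gr$Ue + crossprod(h_prev, d_a)
    gr$be <- gr$be + colSums(d_a)
    d_h <- d_a %*% t(p$Ue)
  }
  for (t in seq_len(T_len)) {
    d_a <- d_hb * (1 - fw$HB[[t]]^2)
    hb_next <- if (t == T_len) matrix(0, N, He) else fw$HB[[t + 1L]]
    gr$Web <- gr$Web + crossprod(X[[t]], d_a)
    gr$Ueb <- gr$Ueb + crossprod(hb_next, d_a)
    gr$beb <- gr$beb + colSums(d_a)
    d_hb <- d_a %*% t(p$Ueb)
  }
  gr
}

#' Fit a Gaussian-emission sequential autoencoder to trial windows
#'
#' Variational sequential autoencoder for continuous neural features: a
#' bidirectional recurrent encoder maps each trial to a Gaussian posterior over
#' the generator's initial condition; an autonomous recurrent generator unrolls
#' from a sampled initial condition; latent factors `f_t` are a time-invariant
#' linear readout of the generator state; and each z-scored feature `x_t` is
#' modeled as Gaussian with mean `W1 f_t + b1` and SD
#' `floor + softplus(W2 f_t + b2)` (both readouts fixed across time). Training
#' maximizes the evidence lower bound (Gaussian log-likelihood minus KL of the
#' initial-condition posterior from a standard-normal prior) by Adam with
#' linear KL warm-up.
#'
#' @param windows a `trial_windows` of z-scored features (trials x time x
#'   features), or a plain 3-d array.
#' @param n_factors latent factor count; default half the feature count,
#'   capped at 16.
#' @param seed integer seed; fully determines initialization and training.
#' @param epochs training epochs (full-batch).
#' @param lr initial Adam learning rate.
#' @param lr_decay per-epoch multiplicative learning-rate decay.
#' @param enc_size,gen_size encoder / generator hidden sizes.
#' @param kl_warmup_frac fraction of epochs over which the KL weight ramps
#'   linearly from 0 to 1.
#' @param sigma_floor lower bound added to the emission SD.
#' @param verbose print loss every 50 epochs.
#' @return A `gaussian_lfads` model: parameter list, sizes, per-epoch loss
#'   history (stochastic training `loss`, `nll`, `kl`, plus `monitor` — the
#'   deterministic posterior-mean ELBO at full KL weight, used to track
#'   convergence without sampling noise), and the training configuration.
#' @export
fit_gaussian_lfads <- function(windows, n_factors = NULL, seed = 1L,
                               epochs = 300L, lr = 0.01, lr_decay = 0.993,
                               enc_size = 32L, gen_size = 48L,
                               kl_warmup_frac = 0.2, sigma_floor = 1e-3,
                               verbose = FALSE) {
  vals <- if (is.list(windows)) windows$values else windows
  stop_if(length(dim(vals)) != 3L, "windows must be a trials x time x features array")
  N <- dim(vals)[1]; T_len <- dim(vals)[2]; Fn <- dim(vals)[3]
  if (is.null(n_factors)) n_factors <- max(1L, min(16L, Fn %/% 2L))
  stop_if(n_factors >= Fn, "n_factors must be smaller than the feature count")
  X <- lapply(seq_len(T_len), function(t) matrix(vals[, t, ], N, Fn))

  set.seed(seed)
  p <- glfads_init(Fn, enc_size, gen_size, n_factors, sigma_floor)
  adam_m <- lapply(p, function(m) m * 0)
  adam_v <- lapply(p, function(m) m * 0)
  b1 <- 0.9; b2 <- 0.999; ad_eps <- 1e-8
  warm <- max(1L, round(kl_warmup_frac * epochs))
  hist <- matrix(NA_real_, epochs, 4,
                 dimnames = list(NULL, c("loss", "nll", "kl", "monitor")))
  for (ep in seq_len(epochs)) {
    beta <- min(1, ep / warm)
    lr_ep <- lr * lr_decay^ep
    eps <- matrix(stats::rnorm(N * gen_size), N, gen_size)
    fw <- glfads_forward(p, X, eps, beta, sigma_floor, keep = TRUE)
    if (!is.finite(fw$loss)) {
      stop("training diverged (non-finite loss) at epoch ", ep,
           " with seed ", seed, call. = FALSE)
    }
    gr <- glfads_backward(p, X, eps, beta, sigma_floor, fw)
    for (nm in names(p)) {
      adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * gr[[nm]]
      adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * gr[[nm]]^2
      mhat <- adam_m[[nm]] / (1 - b1^ep)
      vhat <- adam_v[[nm]] / (1 - b2^ep)
      p[[nm]] <- p[[nm]] - lr_ep * mhat / (sqrt(vhat) + ad_eps)
    }
    hist[ep, ] <- c(fw$loss, fw$nll, fw$kl,
                    glfads_forward(p, X, NULL, 1, sigma_floor)$loss)
    if (verbose && ep %% 50L == 0L) {
      message("epoch ", ep, " loss ", signif(fw$loss, 5))
    }
  }
  structure(list(
    params = p,
    n_factors = as.integer(n_factors), n_features = Fn, n_time = T_len,
    enc_size = as.integer(enc_size), gen_size = as.integer(gen_size),
    sigma_floor = sigma_floor, epochs = as.integer(epochs), lr = lr,
    lr_decay = lr_decay,
    kl_warmup_frac = kl_warmup_frac, seed = as.integer(seed),
    loss_history = as.data.frame(hist),
    final_loss = hist[epochs, "loss"]
  ), class = "gaussian_lfads")
}

#' Denoise trial windows with a trained model
#'
#' Runs the encoder at the posterior mean (no sampling) and unrolls the
#' generator, returning the latent factors, the denoised feature estimate
#' (the emission mean), the emission SDs, and principal components of the
#' denoised features.
#'
#' @param model a `gaussian_lfads` fit.
#' @param windows a `trial_windows` (or 3-d array) with the same feature count
#'   the model was trained on.
#' @return A `latent_trajectories` list: `factors` (trials x time x factors),
#'   `mu` and `sigma` (trials x time x features), `pcs` (trials x time x
#'   components, PCA scores of the denoised features), `pca` (the `prcomp`
#'   fit), `rel_times_s` when available.
#' @export
denoise <- function(model, windows) {
  vals <- if (is.list(windows)) windows$values else windows
  stop_if(length(dim(vals)) != 3L, "windows must be a 3-d array")
  N <- dim(vals)[1]; T_len <- dim(vals)[2]; Fn <- dim(vals)[3]
  stop_if(Fn != model$n_features, "feature-count mismatch: model has ",
          model$n_features, ", windows have ", Fn)
  X <- lapply(seq_len(T_len), function(t) matrix(vals[, t, ], N, Fn))
  fw <- glfads_forward(model$params, X, eps = NULL, beta = 1,
                       sigma_floor = model$sigma_floor, keep = FALSE)
  K <- model$n_factors
  factors <- array(NA_real_, c(N, T_len, K))
  mu <- sigma <- array(NA_real_, c(N, T_len, Fn))
  for (t in seq_len(T_len)) {
    factors[, t, ] <- fw$FAC[[t]]
    mu[, t, ] <- fw$MU[[t]]
    sigma[, t, ] <- fw$SIG[[t]]
  }
  flat_mu <- matrix(aperm(mu, c(2, 1, 3)), N * T_len, Fn)
  pca <- stats::prcomp(flat_mu, center = TRUE, scale. = FALSE)
  n_pc <- ncol(pca$x)
  pcs <- array(aperm(array(pca$x, c(T_len, N, n_pc)), c(2, 1, 3)),
               c(N, T_len, n_pc))
  structure(list(
    factors = factors, mu = mu, sigma = sigma,
    pcs = pcs, pca = pca,
    rel_times_s = if (is.list(windows)) windows$rel_times_s
  ), class = "latent_trajectories")
}

#' Number of principal components needed to reach a variance threshold
#'
#' @param x data matrix (rows = samples); columns are centered before PCA.
#' @param threshold cumulative variance fraction to reach (default 0.9).
#' @return Smallest component count whose cumulative explained variance is at
#'   least `threshold`.
#' @export
pcs_for_variance <- function(x, threshold = 0.9) {
  x <- as.matrix(x)
  stop_if(nrow(x) < 2L, "need at least 2 samples")
  v <- stats::prcomp(x, center = TRUE, scale. = FALSE)$sdev^2
  stop_if(sum(v) == 0, "zero-variance data")
  unname(which(cumsum(v) / sum(v) >= threshold)[1])
}

# flatten trials x time x features to (trial,time) rows; returns matrix plus ids
flatten_windows <- function(vals) {
  d <- dim(vals)
  list(x = matrix(aperm(vals, c(2, 1, 3)), d[1] * d[2], d[3]),
       trial = rep(seq_len(d[1]), each = d[2]),
       time = rep(seq_len(d[2]), times = d[1]))
}

#' @export
print.gaussian_lfads <- function(x, ...) {
  cat("<gaussian_lfads> ", x$n_factors, " factors, ", x$n_features,
      " features, ", x$epochs, " epochs; final loss ",
      signif(x$final_loss, 5), "\n", sep = "")
  invisible(x)
}
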