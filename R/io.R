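SESSION_SCHEMA <- "ecogrip-session"
SESSION_VERSION <- 1L

#' Write a session container to disk
#'
#' Stores the recording (signal, kinematics, force, cue times, channel table),
#' the trial table, optional ground truth and configuration, plus a provenance
#' block (schema version, seed, config hash, package version) in one
#' self-describing RDS file.
#'
#' @param session list with at least `recording`; typically the output of
#'   [simulate_session()].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  rec <- session$recording
  stop_if(is.null(rec), "session has no $recording")
  for (f in c("signal", "fs_hz", "kinematics", "force", "cue_times_s")) {
    stop_if(is.null(rec[[f]]), "recording is missing mandatory field '", f, "'")
  }
  container <- list(
    schema = SESSION_SCHEMA,
    version = SESSION_VERSION,
    recording = rec,
    trials = session$trials,
    ground_truth = session$truth,
    config = session$config,
    provenance = list(
      created = format(Sys.time(), tz = "UTC"),
      seed = session$config$seed %||% NA_integer_,
      config_hash = if (!is.null(session$config)) fnv1a_hash(session$config),
      package_version = as.character(utils::packageVersion("ecogrip"))
    )
  )
  saveRDS(container, path)
  invisible(path)
}

#' Read a session container
#'
#' Validates the schema name and version, checks that all mandatory recording
#' fields are present (error lists any missing), and warns when the stored
#' configuration no longer matches its provenance hash (manual edit).
#'
#' @param path file written by [write_session()].
#' @return The session list: `recording`, `trials`, `truth`, `config`,
#'   `provenance`.
#' @export
read_session <- function(path) {
  stop_if(!file.exists(path), "no such file: ", path)
  cont <- readRDS(path)
  stop_if(!identical(cont$schema, SESSION_SCHEMA),
          "not a session container (expected schema '", SESSION_SCHEMA,
          "', found '", cont$schema %||% "<none>", "')")
  stop_if(!identical(cont$version, SESSION_VERSION),
          "schema version mismatch: expected ", SESSION_VERSION,
          ", found ", cont$version %||% "<none>")
  missing <- setdiff(c("signal", "fs_hz", "kinematics", "force", "cue_times_s"),
                     names(cont$recording))
  stop_if(length(missing) > 0L, "session is missing mandatory field(s): ",
          paste(missing, collapse = ", "))
  if (!is.null(cont$config) && !is.null(cont$provenance$config_hash) &&
      !identical(fnv1a_hash(cont$config), cont$provenance$config_hash)) {
    warning("stored config does not match its provenance hash; ",
            "the container may have been edited")
  }
  list(recording = cont$recording, trials = cont$trials,
       truth = cont$ground_truth, config = cont$config,
       provenance = cont$provenance)
}

run_stage <- function(name, report, fun) {
  t0 <- Sys.time()
  out <- tryCatch(fun(), error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  list(result = out,
       elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
}

#' Run the full analysis pipeline on a synthetic session
#'
#' Executes simulate, feature extraction, behavioral event detection and
#' labeling, continuous movement and force decoding, per-electrode decoding
#' maps with the between- vs within-mode comparison, latent-dynamics
#' denoising, the neural vector angle with its mode test, and behavioral-mode
#' classification (raw and, when enabled, denoised features). Writes the trial
#' table, decoding maps, and NVA angles as CSV and one machine-readable JSON
#' report; returns the report.
#'
#' @param config a [sim_config()] describing the session.
#' @param out_dir output directory (created if needed).
#' @param seed master seed; stage seeds are derived from it. Defaults to the
#'   config's seed.
#' @param decode_folds folds for population decoding (default 11).
#' @param map_folds folds for the per-electrode maps (default 10).
#' @param lfads run the latent-dynamics stage (default TRUE).
#' @param lfads_epochs training epochs for the latent model.
#' @param classify_method classifier for the mode-classification stage.
#' @param n_shuffles label shuffles for the chance distribution (0 skips it).
#' @return The report list (also written to `report.json`), with one section
#'   per stage plus timings and seeds.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = tempfile("ecogrip_"),
                         seed = config$seed,
                         decode_folds = 11L, map_folds = 10L,
                         lfads = TRUE, lfads_epochs = 150L,
                         classify_method = "bagged_trees",
                         n_shuffles = 0L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config$seed <- as.integer(seed)
  report <- list(seed = as.integer(seed), config = unclass(config),
                 stages = list(), timings_s = list())
  add <- function(name, stage, summary) {
    report$stages[[name]] <<- summary
    report$timings_s[[name]] <<- round(stage$elapsed_s, 3)
  }

  sim <- run_stage("simulate", report, function() simulate_session(config))
  ses <- sim$result
  write_session(ses, file.path(out_dir, "session.rds"))
  add("simulate", sim, list(
    n_trials = nrow(ses$trials),
    n_channels = ncol(ses$recording$signal),
    duration_s = round(nrow(ses$recording$signal) / ses$recording$fs_hz, 3),
    planted_shift_mm = ses$truth$planted_shift_mm
  ))

  fe <- run_stage("features", report, function() {
    compute_band_features(ses$recording)
  })
  feats <- fe$result
  add("features", fe, list(
    n_bins = nrow(feats$values), n_features = ncol(feats$values),
    freq_resolution_hz = feats$freq_resolution_hz
  ))

  ev <- run_stage("events", report, function() {
    mv <- kinematic_pc1(ses$recording$kinematics)
    tt <- detect_onsets(mv, ses$recording$force, ses$recording$cue_times_s,
                        ses$recording$fs_hz,
                        force_targets = ses$trials$force_target)
    list(movement = mv, trial_table = tt)
  })
  trial_table <- ev$result$trial_table
  utils::write.csv(trial_table, file.path(out_dir, "trials.csv"),
                   row.names = FALSE)
  add("events", ev, list(
    n_valid_trials = sum(trial_table$valid),
    n_invalid_trials = sum(!trial_table$valid)
  ))

  design <- build_lagged_design(feats, n_lags = 10L)
  labels <- label_modes(trial_table, design$bin_times)

  de <- run_stage("decode", report, function() {
    mv_t <- align_target(ev$result$movement, ses$recording$fs_hz, design$bin_times)
    f_t <- align_target(ses$recording$force, ses$recording$fs_hz, design$bin_times)
    list(movement = crossval_decode(design, mv_t, n_folds = decode_folds),
         force = crossval_decode(design, f_t, n_folds = decode_folds))
  })
  add("decode", de, list(
    movement_fvaf_median = de$result$movement$median,
    movement_fvaf_iqr = de$result$movement$iqr,
    force_fvaf_median = de$result$force$median,
    force_fvaf_iqr = de$result$force$iqr,
    n_folds = decode_folds
  ))

  mp <- run_stage("maps", report, function() {
    lag_bt <- design$bin_times
    mv_t <- align_target(ev$result$movement, ses$recording$fs_hz, lag_bt)
    f_t <- align_target(ses$recording$force, ses$recording$fs_hz, lag_bt)
    mm <- single_electrode_maps(feats, mv_t, mode = "movement",
                                n_folds = map_folds)
    fm <- single_electrode_maps(feats, f_t, mode = "force",
                                n_folds = map_folds)
    list(movement = mm, force = fm, comparison = compare_inter_intra(mm, fm))
  })
  utils::write.csv(rbind(mp$result$movement, mp$result$force),
                   file.path(out_dir, "maps.csv"), row.names = FALSE)
  add("maps", mp, list(
    displacement_mean_mm = mean(mp$result$comparison$displacement_mm),
    displacement_sd_mm = stats::sd(mp$result$comparison$displacement_mm),
    median_d_inter = mp$result$comparison$median_d_inter,
    median_d_intra = mp$result$comparison$median_d_intra,
    p_value = mp$result$comparison$test$p_value
  ))

  valid_tr <- trial_table[trial_table$valid, ]
  windows <- peri_event_windows(feats, valid_tr$force_onset_s)
  win_trials <- valid_tr[windows$trials, ]

  latent_summary <- NULL
  denoised <- NULL
  if (lfads) {
    lf <- run_stage("lfads", report, function() {
      per_band <- lapply(c("low", "high"), function(bd) {
        w <- subset_windows(windows, bd)
        m <- fit_gaussian_lfads(w, seed = seed + 11L, epochs = lfads_epochs)
        list(model = m, traj = denoise(m, w), windows = w)
      })
      names(per_band) <- c("low", "high")
      per_band
    })
    denoised <- lf$result
    latent_summary <- lapply(lf$result, function(b) {
      raw_flat <- flatten_windows(b$windows$values)$x
      den_flat <- flatten_windows(b$traj$mu)$x
      list(final_loss = b$model$final_loss,
           n_factors = b$model$n_factors,
           pcs90_raw = pcs_for_variance(raw_flat),
           pcs90_denoised = pcs_for_variance(den_flat))
    })
    add("lfads", lf, latent_summary)
  }

  nv <- run_stage("nva", report, function() {
    ta <- trial_average_features(windows)
    clus <- select_feature_clusters(ta, k = 3L, seed = seed + 21L)
    res <- nva_time_course(windows, clus, win_trials)
    test <- compare_modes_nva(res, win_trials, band = clus$tags[1])
    list(clustering = clus, result = res, test = test)
  })
  utils::write.csv(nv$result$result$angles, file.path(out_dir, "nva.csv"),
                   row.names = FALSE)
  add("nva", nv, list(
    selected_tags = nv$result$clustering$tags,
    mean_silhouette = nv$result$clustering$mean_silhouette,
    kw_p_value = nv$result$test$p_value
  ))

  cl <- run_stage("classify", report, function() {
    raw <- classify_modes(design$values, labels, method = classify_method,
                          seed = seed + 31L)
    out <- list(raw = raw)
    if (lfads && !is.null(denoised)) {
      den_mat <- do.call(cbind, lapply(denoised, function(b) {
        flatten_windows(b$traj$mu)$x
      }))
      ids <- flatten_windows(denoised[[1]]$traj$mu)
      abs_time <- win_trials$force_onset_s[ids$trial] +
        windows$rel_times_s[ids$time]
      den_labels <- label_modes(win_trials, abs_time)
      out$denoised <- classify_modes(den_mat, den_labels,
                                     method = classify_method,
                                     seed = seed + 31L)
      out$comparison <- compare_inputs(out$raw, out$denoised)
    }
    if (n_shuffles > 0L) {
      out$chance <- chance_level(design$values, labels,
                                 n_shuffles = n_shuffles, seed = seed + 41L)
    }
    out
  })
  cls <- list(
    method = classify_method,
    raw_accuracy_median = cl$result$raw$accuracy_median,
    raw_accuracy_iqr = cl$result$raw$accuracy_iqr
  )
  if (!is.null(cl$result$denoised)) {
    cls$denoised_accuracy_median <- cl$result$denoised$accuracy_median
    cls$raw_vs_denoised_p <- cl$result$comparison$p_value
  }
  if (!is.null(cl$result$chance)) {
    cls$chance_mean <- mean(cl$result$chance)
    cls$chance_q975 <- unname(stats::quantile(cl$result$chance, 0.975))
  }
  add("classify", cl, cls)

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report$out_dir <- out_dir
  invisible(report)
}
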