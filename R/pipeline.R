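# End-to-end pipeline: simulate (or load) -> spectra -> slope track ->
# hypnogram MI with surrogates -> slow waves -> classification -> summary.
# Every stochastic stage consumes a seed derived deterministically from the
# master seed, so identical configurations give identical numeric outputs.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with its default. The
#' configuration round-trips through JSON unchanged
#' (\code{\link{write_config}} / \code{\link{read_config}}).
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param n_epochs hypnogram length in 30 s epochs.
#' @param n_channels EEG channels to simulate.
#' @param fs sampling rate, Hz.
#' @param segment_sec slope-track segment length, s.
#' @param band slope fit band, Hz.
#' @param psd_method spectral estimator.
#' @param halfbandwidth multitaper smoothing halfwidth, Hz.
#' @param n_surrogates MI surrogate count.
#' @param n_perm permutation count for significance tests.
#' @param n_repeats LDA balanced-subsampling repeats.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(seed = 1, n_epochs = 120, n_channels = 2,
                            fs = 200, segment_sec = 30, band = c(30, 45),
                            psd_method = "multitaper", halfbandwidth = 0.5,
                            n_surrogates = 200, n_perm = 1000,
                            n_repeats = 20, out_dir = NULL) {
  structure(list(seed = seed, n_epochs = n_epochs, n_channels = n_channels,
                 fs = fs, segment_sec = segment_sec, band = band,
                 psd_method = psd_method, halfbandwidth = halfbandwidth,
                 n_surrogates = n_surrogates, n_perm = n_perm,
                 n_repeats = n_repeats, out_dir = out_dir),
            class = "pipeline_config")
}

#' Write a pipeline configuration to JSON
#' @param config a \code{pipeline_config}.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a pipeline configuration from JSON
#' @param path JSON path.
#' @return a \code{pipeline_config}.
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x)
}

#' Run the end-to-end synthetic-data pipeline
#'
#' Simulates an overnight recording from the default state profiles and a
#' Markov hypnogram, then runs the full analysis chain: multitaper spectra,
#' time-resolved 30-45 Hz slope, per-channel mutual information with
#' block-swap surrogate calibration, Spearman correlation with hypnogram
#' depth (EMG slope partialled out), per-state slope summaries, slow-wave
#' detection with per-state rates, and balanced LDA discrimination of wake
#' vs REM from the slope versus from slow-wave power, plus the GLM variance
#' decomposition. With \code{out_dir} set, writes the CSV/JSON artifacts and
#' a summary carrying every seed and parameter.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param rec,hyp optionally, a pre-existing recording and hypnogram to
#'   analyse instead of simulating (both or neither).
#' @return list of stage results (class \code{"pipeline_report"}).
#' @export
run_pipeline <- function(config = pipeline_config(), rec = NULL, hyp = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  profiles <- state_profiles()
  if (is.null(rec) != is.null(hyp))
    stop("provide both 'rec' and 'hyp', or neither")
  simulated <- is.null(rec)
  truth <- NULL
  if (simulated) {
    hyp <- gen_hypnogram(config$n_epochs, sleep_transition_matrix(), "W",
                         seed = child_seed(config$seed, 1))
    sim <- gen_recording(profiles, hyp, n_channels = config$n_channels,
                         fs = config$fs, seed = child_seed(config$seed, 2))
    rec <- sim$recording
    truth <- sim$truth
  }
  eeg_idx <- which(rec$channel_roles == "EEG")
  emg_idx <- which(rec$channel_roles == "EMG")

  track <- time_resolved_slope(rec, segment_sec = config$segment_sec,
                               band = config$band,
                               psd_method = config$psd_method,
                               halfbandwidth = config$halfbandwidth)
  # per-channel MI with surrogate calibration
  mi <- lapply(eeg_idx, function(ch) {
    al <- align_to_hypnogram(track, hyp, channel = ch)
    sl <- rep(NA_real_, length(hyp$labels)); sl[al$epoch] <- al$slope
    tryCatch(suppressWarnings(
      mi_surrogate_test(sl, hyp, n_surrogates = config$n_surrogates,
                        seed = child_seed(config$seed, 10 + ch))),
      error = function(e) NULL)   # e.g. single-stage nights
  })
  names(mi) <- rec$channel_labels[eeg_idx]
  mi <- Filter(Negate(is.null), mi)

  # depth correlation with EMG-slope covariate
  al1 <- align_to_hypnogram(track, hyp, channel = eeg_idx[1])
  covar <- if (length(emg_idx)) {
    alE <- align_to_hypnogram(track, hyp, channel = emg_idx[1])
    ce <- rep(NA_real_, length(hyp$labels)); ce[alE$epoch] <- alE$slope
    ce[al1$epoch]
  } else NULL
  sl1 <- al1$slope
  hyp1 <- hypnogram(al1$stage, hyp$epoch_sec)
  depth_cor <- tryCatch(
    correlate_with_hypnogram(sl1, hyp1, covariate = covar),
    error = function(e) NULL)   # degenerate (single-stage) nights


  summary_states <- state_summary(track, hyp, states = c("W", "N2", "N3", "REM"),
                                  channels = eeg_idx)

  events <- detect_slow_waves(rec, channel = eeg_idx[1], hyp = hyp)
  rates <- event_rate_by_state(events, hyp)

  # per-epoch features on the scoring grid for classification
  psd <- compute_psd(rec, config$psd_method, segment_sec = hyp$epoch_sec,
                     halfbandwidth = config$halfbandwidth,
                     fmax = min(45, rec$fs / 2))
  so_pow <- log10(vapply(seq_len(dim(psd$per_segment)[1]), function(s) {
    sel <- psd$freqs < 1.25
    mean(psd$per_segment[s, eeg_idx[1], sel])
  }, 0))
  n_feat <- min(length(so_pow), length(hyp$labels))
  feat <- data.frame(stage = hyp$labels[seq_len(n_feat)],
                     slope = {
       alf <- align_to_hypnogram(track, hyp, channel = eeg_idx[1])
       v <- rep(NA_real_, length(hyp$labels)); v[alf$epoch] <- alf$slope
       v[seq_len(n_feat)]
                     },
                     so_power = so_pow[seq_len(n_feat)])
  feat <- feat[stats::complete.cases(feat), ]
  wr <- feat[feat$stage %in% c("W", "REM"), ]
  classif <- NULL; glm_fit <- NULL
  if (length(unique(wr$stage)) == 2 && all(table(wr$stage) >= 2)) {
    classif <- list(
      slope = lda_balanced_cv(wr$slope, wr$stage, n_repeats = config$n_repeats,
                              seed = child_seed(config$seed, 30)),
      so_power = lda_balanced_cv(wr$so_power, wr$stage,
                                 n_repeats = config$n_repeats,
                                 seed = child_seed(config$seed, 31)))
    if (nrow(wr) >= 10)
      glm_fit <- glm_state_model(as.integer(wr$stage == "REM"), wr$slope,
                                 wr$so_power)
  }

  report <- structure(list(
    config = config, simulated = simulated, truth = truth,
    recording = rec, hypnogram = hyp, track = track,
    mi = mi, depth_cor = depth_cor, state_summary = summary_states,
    events = events, event_rates = rates,
    classification = classif, glm = glm_fit), class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  %d epochs, %d channel(s) @ %g Hz%s\n",
              length(x$hypnogram$labels), nrow(x$recording$data),
              x$recording$fs, if (x$simulated) " (simulated)" else ""))
  for (nm in names(x$mi))
    cat(sprintf("  MI(%s): %.3f bits, z = %.1f\n", nm, x$mi[[nm]]$observed,
                x$mi[[nm]]$z))
  if (!is.null(x$classification))
    cat(sprintf("  W-vs-REM LDA: slope %.1f%%, SO power %.1f%%\n",
                x$classification$slope$accuracy,
                x$classification$so_power$accuracy))
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  export_track_csv(report$track, file.path(out_dir, "slope_track.csv"))
  utils::write.csv(report$state_summary,
                   file.path(out_dir, "state_summary.csv"), row.names = FALSE)
  utils::write.csv(report$events, file.path(out_dir, "slow_waves.csv"),
                   row.names = FALSE)
  utils::write.csv(report$event_rates, file.path(out_dir, "event_rates.csv"),
                   row.names = FALSE)
  write_hypnogram(report$hypnogram, file.path(out_dir, "hypnogram.txt"))
  mi_tab <- do.call(rbind, lapply(names(report$mi), function(nm) {
    m <- report$mi[[nm]]
    data.frame(channel = nm, statistic = "mutual_information",
               observed = m$observed, surrogate_mean = m$surrogate_mean,
               surrogate_sd = m$surrogate_sd, z = m$z, p = m$p_two_tailed)
  }))
  utils::write.csv(mi_tab, file.path(out_dir, "mi_surrogates.csv"),
                   row.names = FALSE)
  summary <- list(
    package_version = as.character(utils::packageVersion("slopetrack")),
    config = unclass(report$config),
    mi_z = vapply(report$mi, `[[`, 0, "z"),
    depth_rho = report$depth_cor$rho,
    classification = if (!is.null(report$classification)) list(
      slope_acc = report$classification$slope$accuracy,
      so_acc = report$classification$so_power$accuracy) else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
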