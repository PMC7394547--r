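# Slow-wave detection and slow-wave-locked slope dynamics.

#' Detect slow waves on one channel
#'
#' The channel is bandpass filtered between \code{band[1]} and \code{band[2]}
#' Hz with a zero-phase Butterworth cascade (the filtering runs on an
#' anti-aliased decimated copy near 100 Hz, where the very low corner
#' frequencies are numerically well conditioned). Candidate events span
#' successive positive-to-negative zero crossings of the filtered trace (one
#' trough followed by one peak); candidates are kept when their duration lies
#' in \code{duration_range} and their trough-to-peak amplitude reaches the
#' \code{amplitude_percentile}-th percentile of all duration-valid candidates
#' on the channel. The trough is the filtered-signal minimum inside the
#' candidate; with a hypnogram, each event is labelled with the stage at its
#' trough.
#'
#' @param rec a \code{\link{recording}} of at least 30 s.
#' @param channel channel index.
#' @param hyp optional \code{\link{hypnogram}} for stage labelling.
#' @param band bandpass corner frequencies, Hz.
#' @param duration_range admissible event durations, s.
#' @param amplitude_percentile percentile (0-100) of candidate amplitudes used
#'   as the selection threshold.
#' @param amplitude_measure \code{"p2p"} (trough-to-peak, default) or
#'   \code{"trough"} (trough depth).
#' @return data.frame (channel, trough_time_s, start_s, end_s, duration_s,
#'   p2p_uv, state), sorted by trough time; empty with a warning when fewer
#'   than 4 candidates exist.
#' @export
detect_slow_waves <- function(rec, channel = 1, hyp = NULL,
                              band = c(0.16, 1.25),
                              duration_range = c(0.8, 2),
                              amplitude_percentile = 75,
                              amplitude_measure = c("p2p", "trough")) {
  amplitude_measure <- match.arg(amplitude_measure)
  if (duration(rec) < 30) stop("recording must span at least 30 s")
  x <- rec$data[channel, ]
  fs <- rec$fs
  dec <- max(1L, floor(fs / 100))
  if (dec > 1L) {
    x <- signal::decimate(x, dec)
    fs <- fs / dec
  }
  filt <- filter_slow_band(x, fs, band)
  # positive-to-negative zero crossings delimit candidates
  s <- sign(filt)
  p2n <- which(s[-length(s)] > 0 & s[-1] <= 0)
  empty <- data.frame(channel = character(0), trough_time_s = numeric(0),
                      start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0), p2p_uv = numeric(0),
                      state = character(0), stringsAsFactors = FALSE)
  if (length(p2n) < 2) { warning("too few zero crossings; no events"); return(empty) }
  starts <- p2n[-length(p2n)]
  ends <- p2n[-1]
  durs <- (ends - starts) / fs
  keep_dur <- durs >= duration_range[1] & durs <= duration_range[2]
  if (sum(keep_dur) < 4) {
    warning("fewer than 4 duration-valid candidates; amplitude percentile unreliable, returning no events")
    return(empty)
  }
  starts <- starts[keep_dur]; ends <- ends[keep_dur]; durs <- durs[keep_dur]
  trough_idx <- integer(length(starts)); amp <- numeric(length(starts))
  for (i in seq_along(starts)) {
    idx <- starts[i]:ends[i]
    ti <- idx[which.min(filt[idx])]
    trough_idx[i] <- ti
    after <- ti:ends[i]
    amp[i] <- if (amplitude_measure == "p2p")
      max(filt[after]) - filt[ti] else -filt[ti]
  }
  thr <- stats::quantile(amp, amplitude_percentile / 100, names = FALSE)
  # noise floor: a slow wave far smaller than the broadband signal is not a
  # physiological event, whatever its rank among candidates
  thr <- max(thr, 0.05 * stats::sd(x))
  keep <- amp >= thr
  tt <- (trough_idx[keep] - 1L) / fs
  st <- if (!is.null(hyp)) {
    ep <- pmin(floor(tt / hyp$epoch_sec) + 1L, length(hyp$labels))
    hyp$labels[ep]
  } else rep(NA_character_, sum(keep))
  out <- data.frame(channel = rep(rec$channel_labels[channel], sum(keep)),
                    trough_time_s = tt,
                    start_s = (starts[keep] - 1L) / fs,
                    end_s = (ends[keep] - 1L) / fs,
                    duration_s = durs[keep],
                    p2p_uv = amp[keep],
                    state = st, stringsAsFactors = FALSE)
  out[order(out$trough_time_s), ]
}

# Zero-phase bandpass for the slow-oscillation band: 2nd-order Butterworth
# low- and high-pass applied forward-backward (4th order effective each).
filter_slow_band <- function(x, fs, band) {
  lo <- signal::butter(2, band[2] / (fs / 2), type = "low")
  hi <- signal::butter(2, band[1] / (fs / 2), type = "high")
  signal::filtfilt(hi, signal::filtfilt(lo, x))
}

#' Slow-wave-locked slope time course
#'
#' Epochs the raw channel around each event trough (+/- \code{window} s;
#' events too close to the recording edges are dropped), runs the sliding
#' single-taper spectral decomposition (\code{\link{event_tfr}}: 0.5 s
#' windows, 0.25 s step, +/- 2 Hz smoothing) and fits the 30-45 Hz log-log
#' slope in every window. Returns per-event courses and their mean +/- SEM.
#'
#' @param rec a \code{\link{recording}}.
#' @param events event table from \code{\link{detect_slow_waves}}.
#' @param channel channel index the events refer to.
#' @param window half-width of the event epoch, s.
#' @param band slope fit band, Hz.
#' @return list with \code{centers} (window centers, s, relative to trough),
#'   \code{mean_slope}, \code{sem_slope}, \code{per_event}
#'   (events x windows), and \code{events_used}.
#' @export
event_locked_slope <- function(rec, events, channel = 1, window = 2.5,
                               band = c(30, 45)) {
  fs <- rec$fs
  n <- ncol(rec$data)
  half <- as.integer(round(window * fs))
  centers_idx <- as.integer(round(events$trough_time_s * fs)) + 1L
  ok <- centers_idx - half >= 1L & centers_idx + half - 1L <= n
  if (!any(ok)) stop("no events fully inside the recording after windowing")
  events <- events[ok, , drop = FALSE]
  centers_idx <- centers_idx[ok]
  epochs <- t(vapply(centers_idx, function(ci)
    rec$data[channel, (ci - half):(ci + half - 1L)], numeric(2L * half)))
  tfr <- event_tfr(epochs, fs)
  sel <- tfr$freqs >= band[1] & tfr$freqs <= band[2]
  if (sum(sel) < 3) stop("too few frequency bins inside the fit band")
  lf <- log10(tfr$freqs[sel])
  n_ev <- dim(tfr$power)[1]; n_win <- dim(tfr$power)[2]
  courses <- matrix(NA_real_, n_ev, n_win)
  for (ev in seq_len(n_ev)) {
    for (w in seq_len(n_win)) {
      p <- tfr$power[ev, w, sel]
      if (anyNA(p) || any(p <= 0)) next
      fit <- stats::lm.fit(cbind(1, lf), log10(p))
      courses[ev, w] <- unname(fit$coefficients[2])
    }
  }
  list(centers = tfr$centers,
       mean_slope = colMeans(courses, na.rm = TRUE),
       sem_slope = apply(courses, 2, sem),
       per_event = courses,
       events_used = events)
}

#' Slow-wave incidence per state
#'
#' Events per minute of each stage: events whose trough falls in the stage,
#' divided by the minutes scored as that stage. Stages with zero scored time
#' are reported as missing.
#'
#' @param events event table with a \code{state} column (or a hypnogram to
#'   label from).
#' @param hyp a \code{\link{hypnogram}} covering the event times.
#' @param states states to report.
#' @return data.frame (state, n_events, minutes, rate_per_min).
#' @export
event_rate_by_state <- function(events, hyp, states = c("W", "N3", "REM")) {
  st <- events$state
  if (all(is.na(st))) {
    ep <- pmin(floor(events$trough_time_s / hyp$epoch_sec) + 1L,
               length(hyp$labels))
    st <- hyp$labels[ep]
  }
  do.call(rbind, lapply(states, function(s) {
    minutes <- sum(hyp$labels == s) * hyp$epoch_sec / 60
    n_ev <- sum(st == s, na.rm = TRUE)
    data.frame(state = s, n_events = n_ev, minutes = minutes,
               rate_per_min = if (minutes > 0) n_ev / minutes else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Trough-window slope by state
#'
#' Groups the slope of the trough-centered window (the window whose center is
#' closest to lag zero) by the stage each event occurred in. States without
#' events are reported as missing.
#'
#' @param locked output of \code{\link{event_locked_slope}}.
#' @param states states to report.
#' @return data.frame (state, mean_trough_slope, sem, n_events).
#' @export
trough_slope_by_state <- function(locked, states = c("W", "N3", "REM")) {
  w0 <- which.min(abs(locked$centers))
  v <- locked$per_event[, w0]
  st <- locked$events_used$state
  do.call(rbind, lapply(states, function(s) {
    vi <- v[!is.na(v) & st == s]
    data.frame(state = s,
               mean_trough_slope = if (length(vi)) mean(vi) else NA_real_,
               sem = if (length(vi) > 1) stats::sd(vi) / sqrt(length(vi)) else NA_real_,
               n_events = length(vi), stringsAsFactors = FALSE)
  }))
}
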