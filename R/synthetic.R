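# Synthetic polysomnography generator.
#
# Real overnight recordings are large and access-restricted; every downstream
# stage of the package is therefore exercised on surrogate data whose
# statistical structure matches what the analysis assumes: a per-state 1/f
# background (steepest in REM, shallowest in wake), band-limited oscillations
# (slow oscillations, spindles, alpha), slow-wave events at state-dependent
# rates, and a broadband EMG channel.

#' Generate a 1/f power-law signal
#'
#' Shapes white Gaussian noise in the frequency domain so that the power
#' spectral density follows \eqn{f^{slope}} over a validity band (flat below
#' \code{f_lo} to keep the variance finite for steep exponents). The result is
#' demeaned and scaled to unit variance.
#'
#' @param n_samples number of samples (at least \code{2*fs}).
#' @param fs sampling rate, Hz.
#' @param slope spectral exponent (log-log slope of the PSD), must be <= 0.
#' @param seed integer seed; the signal is fully reproducible given the seed.
#' @param f_lo lower edge (Hz) of the power-law validity band; the spectrum is
#'   flat below it.
#' @return numeric vector of length \code{n_samples}, zero mean, unit variance.
#' @export
gen_powerlaw_signal <- function(n_samples, fs, slope, seed = NULL, f_lo = 1) {
  stopifnot_scalar(fs, "fs"); stopifnot_scalar(slope, "slope")
  if (fs <= 0) stop("'fs' must be positive")
  if (slope > 0) stop("'slope' must be <= 0 (aperiodic decay)")
  if (n_samples < 2 * fs) stop("'n_samples' must be at least 2*fs")
  n <- as.integer(n_samples)
  with_seed(seed, {
    x <- stats::rnorm(n)
    X <- stats::fft(x)
    k <- 0:(n - 1L)
    f <- pmin(k, n - k) * fs / n        # two-sided frequency magnitude
    amp <- pmax(f, f_lo)^(slope / 2)    # PSD ~ f^slope  =>  amplitude ~ f^(slope/2)
    amp[1L] <- 0                        # no DC
    y <- Re(stats::fft(X * amp, inverse = TRUE)) / n
    y <- y - mean(y)
    y / stats::sd(y)
  })
}

#' Generate band-limited oscillation bursts
#'
#' A sinusoidal carrier with random phase, gated by a smoothed on/off envelope
#' so that the oscillation is active for about \code{duty} of the samples.
#' Burst on/off transitions are raised-cosine ramped to avoid spectral edges.
#'
#' @param freq carrier frequency, Hz (must lie below Nyquist).
#' @param amplitude peak amplitude in signal units.
#' @param duty fraction of time the oscillation is active, in [0, 1].
#' @param n_samples,fs signal length and sampling rate.
#' @param seed integer seed.
#' @param burst_sec nominal burst length in seconds used to tile the envelope.
#' @return numeric vector of length \code{n_samples}.
#' @export
gen_oscillation_burst <- function(freq, amplitude, duty, n_samples, fs,
                                  seed = NULL, burst_sec = 1) {
  if (duty < 0 || duty > 1) stop("'duty' must lie in [0, 1]")
  if (freq <= 0 || freq >= fs / 2) stop("'freq' must lie in (0, Nyquist)")
  n <- as.integer(n_samples)
  if (duty == 0) return(numeric(n))
  with_seed(seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    t <- (0:(n - 1L)) / fs
    carrier <- sin(2 * pi * freq * t + phase)
    if (duty >= 1) {
      env <- rep(1, n)
    } else {
      n_chunk <- max(1L, as.integer(round(burst_sec * fs)))
      n_chunks <- ceiling(n / n_chunk)
      on <- stats::runif(n_chunks) < duty
      env <- rep(as.numeric(on), each = n_chunk)[seq_len(n)]
      # raised-cosine smoothing of the gate (~100 ms ramps)
      ramp <- max(3L, as.integer(round(0.1 * fs)))
      kern <- 0.5 * (1 - cos(2 * pi * seq_len(ramp) / (ramp + 1)))
      kern <- kern / sum(kern)
      env <- as.numeric(stats::filter(c(rep(env[1], ramp), env, rep(env[n], ramp)),
                                      kern, sides = 2))[ramp + seq_len(n)]
    }
    amplitude * env * carrier
  })
}

#' Simulate a hypnogram as a first-order Markov chain
#'
#' @param n_epochs number of 30 s epochs to draw.
#' @param transition_matrix row-stochastic matrix with stage names on rows and
#'   columns; rows must sum to 1 within 1e-9.
#' @param initial_state starting stage label (must be a row name).
#' @param seed integer seed.
#' @param epoch_sec epoch length, seconds.
#' @return a \code{\link{hypnogram}}.
#' @export
gen_hypnogram <- function(n_epochs, transition_matrix, initial_state,
                          seed = NULL, epoch_sec = 30) {
  tm <- as.matrix(transition_matrix)
  states <- rownames(tm)
  if (is.null(states) || is.null(colnames(tm)) ||
      !identical(states, colnames(tm)))
    stop("'transition_matrix' needs identical row and column stage names")
  if (any(abs(rowSums(tm) - 1) > 1e-9))
    stop("rows of 'transition_matrix' must sum to 1")
  if (any(tm < 0)) stop("transition probabilities must be non-negative")
  if (!initial_state %in% states) stop("'initial_state' not among the states")
  with_seed(seed, {
    labs <- character(n_epochs)
    cur <- initial_state
    for (e in seq_len(n_epochs)) {
      labs[e] <- cur
      cur <- sample(states, 1L, prob = tm[cur, ])
    }
    hypnogram(labs, epoch_sec = epoch_sec)
  })
}

#' Default overnight stage-transition matrix
#'
#' Stay probabilities give realistic dwell times at 30 s epochs (mean dwell
#' 1/(1-p) epochs: consolidated N2/N3/REM bouts of several minutes, brief
#' N1), and the stationary distribution approximates a healthy night's stage
#' composition (W 13%, N1 6%, N2 39%, N3 24%, REM 18%).
#' @return row-stochastic 5x5 matrix over W, N1, N2, N3, REM.
#' @export
sleep_transition_matrix <- function() {
  m <- matrix(0, 5, 5, dimnames = list(c("W", "N1", "N2", "N3", "REM"),
                                       c("W", "N1", "N2", "N3", "REM")))
  m["W", ]   <- c(0.90, 0.10, 0.00, 0.00, 0.00)
  m["N1", ]  <- c(0.05, 0.55, 0.38, 0.00, 0.02)
  m["N2", ]  <- c(0.01, 0.02, 0.88, 0.06, 0.03)
  m["N3", ]  <- c(0.01, 0.00, 0.09, 0.90, 0.00)
  m["REM", ] <- c(0.02, 0.03, 0.02, 0.00, 0.93)
  m
}

#' Inject biphasic slow-wave events into a zero signal
#'
#' Places non-overlapping trough-then-peak waveforms (one full cycle of
#' \eqn{-\sin}) with durations drawn uniformly from \code{duration_range},
#' at an average rate of \code{rate} events per minute, and returns the exact
#' ground-truth trough times.
#'
#' @param rate events per minute.
#' @param amplitude half peak-to-peak amplitude in signal units.
#' @param duration_range length-2 numeric, event duration bounds in seconds
#'   (within (0, 5]).
#' @param n_samples,fs signal length and sampling rate.
#' @param seed integer seed.
#' @return list with \code{signal} (numeric vector), \code{trough_times},
#'   \code{onsets}, \code{durations} (all seconds).
#' @export
gen_slow_waves <- function(rate, amplitude, duration_range = c(0.8, 2),
                           n_samples, fs, seed = NULL) {
  if (any(duration_range <= 0) || any(duration_range > 5))
    stop("'duration_range' must lie within (0, 5] seconds")
  if (rate < 0) stop("'rate' must be non-negative")
  n <- as.integer(n_samples)
  total_sec <- n / fs
  sig <- numeric(n)
  if (rate == 0)
    return(list(signal = sig, trough_times = numeric(0),
                onsets = numeric(0), durations = numeric(0)))
  n_events <- round(rate * total_sec / 60)
  if (n_events == 0)
    return(list(signal = sig, trough_times = numeric(0),
                onsets = numeric(0), durations = numeric(0)))
  slot <- total_sec / n_events
  if (slot < max(duration_range))
    stop("slow-wave rate too high: non-overlapping placement infeasible")
  with_seed(seed, {
    # one event per equal time slot, jittered within the slot: non-overlap
    # is guaranteed while onsets stay irregular
    kept_durs <- stats::runif(n_events, duration_range[1], duration_range[2])
    onsets <- (seq_len(n_events) - 1L) * slot +
      stats::runif(n_events) * (slot - kept_durs)
    troughs <- numeric(length(onsets))
    for (i in seq_along(onsets)) {
      i0 <- as.integer(round(onsets[i] * fs))
      nd <- as.integer(round(kept_durs[i] * fs))
      idx <- i0 + seq_len(nd)
      idx <- idx[idx >= 1L & idx <= n]
      tt <- (idx - 1L - i0) / fs
      sig[idx] <- sig[idx] - amplitude * sin(2 * pi * tt / kept_durs[i])
      troughs[i] <- onsets[i] + kept_durs[i] / 4   # minimum of -sin over one cycle
    }
    list(signal = sig, trough_times = troughs, onsets = onsets,
         durations = kept_durs)
  })
}

#' Arousal-state signal profiles
#'
#' Returns one profile per state: target aperiodic slope, oscillations
#' (center Hz, bandwidth Hz, relative amplitude, burst duty cycle), slow-wave
#' rate per minute, and relative broadband EMG level. Target slopes default to
#' published group means for wake (-1.84), N2 (-3.67), N3 (-3.46), REM (-4.73)
#' and propofol anesthesia (-3.10); N1, oscillation amplitudes, duty cycles and
#' EMG levels are generator choices documented in the methods vignette.
#'
#' @return named list of state profiles.
#' @export
state_profiles <- function() {
  osc <- function(freq, bw, amp, duty) list(freq = freq, bw = bw, amp = amp, duty = duty)
  list(
    W = list(target_slope = -1.84,
             oscillations = list(osc(10, 2, 0.8, 0.6)),   # posterior alpha
             slow_wave_rate = 5.05, emg_level = 1.0),
    N1 = list(target_slope = -3.0,
              oscillations = list(osc(5, 2, 0.4, 0.3)),
              slow_wave_rate = 5, emg_level = 0.4),
    N2 = list(target_slope = -3.67,
              oscillations = list(osc(13.5, 2, 0.6, 0.25)), # sleep spindles
              slow_wave_rate = 15, emg_level = 0.25),
    N3 = list(target_slope = -3.46,
              oscillations = list(osc(13.5, 2, 0.3, 0.1)),
              slow_wave_rate = 28.79, emg_level = 0.2),
    REM = list(target_slope = -4.73,
               oscillations = list(osc(6, 2, 0.3, 0.3)),   # theta
               slow_wave_rate = 2.16, emg_level = 0.05),   # atonia
    ANESTHESIA = list(target_slope = -3.10,
                      oscillations = list(osc(10, 2, 0.5, 0.5)), # frontal alpha
                      slow_wave_rate = 20, emg_level = 0.1)
  )
}

validate_profile <- function(p, fs, state) {
  if (!is.numeric(p$target_slope) || p$target_slope >= 0)
    stop("profile for ", state, ": target_slope must be negative")
  for (o in p$oscillations) {
    if (o$freq <= 0 || o$freq >= fs / 2)
      stop("profile for ", state, ": oscillation frequency outside (0, Nyquist)")
    if (o$duty < 0 || o$duty > 1)
      stop("profile for ", state, ": duty cycle outside [0, 1]")
  }
  invisible(TRUE)
}

#' Simulate a multichannel recording from state profiles and a hypnogram
#'
#' Builds each 30 s epoch from its state's profile (unit-variance 1/f
#' background plus oscillation bursts plus slow waves), cross-fades adjacent
#' epochs over 1 s cosine ramps to avoid spectral edge artifacts, and appends
#' one EMG channel (Gaussian noise high-pass filtered above 40 Hz, scaled by
#' the state's EMG level). Fully reproducible from the seed.
#'
#' @param profiles named list of state profiles (see \code{\link{state_profiles}});
#'   every hypnogram label must have an entry.
#' @param hyp a \code{\link{hypnogram}}.
#' @param n_channels number of EEG channels (an EMG channel is appended).
#' @param fs sampling rate, Hz.
#' @param seed master integer seed.
#' @param sw_amplitude slow-wave amplitude in background-SD units.
#' @return list with \code{recording} and \code{truth}; truth carries per-epoch
#'   state and generating slope, per-channel ground-truth trough times, and the
#'   seed.
#' @export
gen_recording <- function(profiles, hyp, n_channels = 2, fs = 400, seed = 1,
                          sw_amplitude = 4) {
  labs <- hyp$labels
  missing_p <- setdiff(unique(labs), names(profiles))
  if (length(missing_p))
    stop("no profile for state(s): ", paste(missing_p, collapse = ", "))
  for (s in unique(labs)) validate_profile(profiles[[s]], fs, s)
  n_ep <- as.integer(round(hyp$epoch_sec * fs))
  n_ramp <- as.integer(round(1 * fs))          # 1 s cosine cross-fade
  n_epochs <- length(labs)
  n <- n_epochs * n_ep
  dat <- matrix(0, n_channels + 1L, n)
  troughs <- vector("list", n_channels)
  rise <- 0.5 * (1 - cos(pi * seq_len(n_ramp) / n_ramp))
  for (ch in seq_len(n_channels)) {
    acc <- numeric(n); wacc <- numeric(n)
    ch_troughs <- numeric(0)
    for (e in seq_len(n_epochs)) {
      p <- profiles[[labs[e]]]
      sd_e <- child_seed(seed, (ch - 1L) * n_epochs + e)
      len <- if (e < n_epochs) n_ep + n_ramp else n_ep
      x <- gen_powerlaw_signal(len, fs, p$target_slope, seed = sd_e)
      k <- 1L
      for (o in p$oscillations) {
        x <- x + gen_oscillation_burst(o$freq, o$amp, o$duty, len, fs,
                                       seed = child_seed(sd_e, 10 + k))
        k <- k + 1L
      }
      sw <- gen_slow_waves(p$slow_wave_rate, sw_amplitude, c(0.8, 2), len, fs,
                           seed = child_seed(sd_e, 99))
      x <- x + sw$signal
      start <- (e - 1L) * n_ep
      # keep only troughs attributed to this epoch's own 30 s slot
      tt <- sw$trough_times + start / fs
      ch_troughs <- c(ch_troughs, tt[sw$trough_times < n_ep / fs])
      w <- rep(1, len)
      if (e > 1L) w[seq_len(n_ramp)] <- rise
      if (e < n_epochs) w[len - n_ramp + seq_len(n_ramp)] <- rev(rise)
      idx <- start + seq_len(len)
      keep <- idx <= n
      acc[idx[keep]] <- acc[idx[keep]] + (x * w)[keep]
      wacc[idx[keep]] <- wacc[idx[keep]] + w[keep]
    }
    dat[ch, ] <- acc / pmax(wacc, .Machine$double.eps)
    troughs[[ch]] <- sort(ch_troughs)
  }
  # EMG channel: broadband noise high-passed above 40 Hz, per-state amplitude
  emg_noise <- with_seed(child_seed(seed, 777), stats::rnorm(n))
  bf <- signal::butter(4, min(40 / (fs / 2), 0.95), type = "high")
  emg_noise <- signal::filtfilt(bf, emg_noise)
  emg_noise <- emg_noise / stats::sd(emg_noise)
  env <- rep(vapply(labs, function(s) profiles[[s]]$emg_level, 0), each = n_ep)
  ramp_k <- rep(1 / n_ramp, n_ramp)
  env <- as.numeric(stats::filter(c(rep(env[1], n_ramp), env, rep(env[n], n_ramp)),
                                  ramp_k, sides = 2))[n_ramp + seq_len(n)]
  dat[n_channels + 1L, ] <- emg_noise * env
  rec <- recording(dat, fs,
                   channel_labels = c(paste0("EEG", seq_len(n_channels)), "EMG"),
                   channel_roles = c(rep("EEG", n_channels), "EMG"))
  truth <- structure(list(
    states = labs,
    slopes = vapply(labs, function(s) profiles[[s]]$target_slope, 0,
                    USE.NAMES = FALSE),
    trough_times = troughs,
    epoch_sec = hyp$epoch_sec,
    seed = seed), class = "synth_truth")
  stopifnot(all(unlist(troughs) >= 0), all(unlist(troughs) <= n / fs))
  list(recording = rec, truth = truth)
}
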