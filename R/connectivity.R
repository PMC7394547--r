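# Fronto-parietal connectivity controls.
#
# Coherence mixes power and phase effects, so phase locking (PLV/iPLV) and
# (orthogonalized) power-envelope correlations are computed alongside it; all
# are scored per 30 s epoch and compared against the slope track by hypnogram
# mutual information.

# Analytic signal via the frequency-domain Hilbert construction.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

bandpass_filter <- function(x, fs, band, order = 3) {
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

#' Magnitude-squared coherence of a channel pair
#'
#' Welch cross-spectral coherence: Hann sub-windows with 50 percent overlap,
#' |Sxy|^2 / (Sxx Syy), averaged over the requested band (theta 4-10 Hz by
#' default). With fewer than 4 sub-windows the estimate is refused (the
#' estimator's bias scales as 1/n_windows).
#'
#' @param x,y equal-length signals.
#' @param fs sampling rate, Hz.
#' @param band frequency band averaged, Hz.
#' @param win_sec sub-window length, s.
#' @return band-mean magnitude-squared coherence in [0, 1].
#' @export
coherence_pair <- function(x, y, fs, band = c(4, 10), win_sec = 4) {
  n <- length(x)
  nwin <- as.integer(round(win_sec * fs))
  step <- nwin %/% 2L
  if (n < nwin + 3L * step) stop("need at least 4 sub-windows per epoch")
  starts <- seq(1L, n - nwin + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(nwin - 1L)) / (nwin - 1L)))
  nf <- floor(nwin / 2) + 1L
  sxx <- syy <- numeric(nf); sxy <- complex(nf)
  for (s in starts) {
    idx <- s + seq_len(nwin) - 1L
    X <- stats::fft(w * demean_detrend(x[idx]))[seq_len(nf)]
    Y <- stats::fft(w * demean_detrend(y[idx]))[seq_len(nf)]
    sxx <- sxx + Mod(X)^2
    syy <- syy + Mod(Y)^2
    sxy <- sxy + X * Conj(Y)
  }
  if (all(sxx == 0) || all(syy == 0)) stop("zero power")
  msc <- Mod(sxy)^2 / (sxx * syy)
  f <- (0:(nf - 1L)) * fs / nwin
  sel <- f >= band[1] & f <= band[2]
  mean(msc[sel])
}

#' Phase-locking value and its imaginary part
#'
#' Band-limits both signals, extracts analytic phases, and reports
#' PLV = |mean exp(i dphi)| together with iPLV = |mean Im exp(i dphi)|,
#' which discounts zero-lag (volume-conduction-like) coupling. Filter edges
#' (1 s each side) are trimmed before averaging.
#'
#' @param x,y equal-length signals.
#' @param fs sampling rate, Hz.
#' @param band frequency band, Hz (must fit below Nyquist).
#' @return list with \code{plv} and \code{iplv}, both in [0, 1].
#' @export
phase_locking_pair <- function(x, y, fs, band = c(4, 10)) {
  if (band[2] >= fs / 2) stop("band exceeds the Nyquist frequency")
  ax <- analytic_signal(bandpass_filter(x, fs, band))
  ay <- analytic_signal(bandpass_filter(y, fs, band))
  trim <- as.integer(fs)
  keep <- (trim + 1):(length(x) - trim)
  dphi <- Arg(ax[keep]) - Arg(ay[keep])
  e <- exp(1i * dphi)
  list(plv = Mod(mean(e)), iplv = abs(mean(Im(e))))
}

#' (Orthogonalized) power-envelope correlation
#'
#' Correlates the log power envelopes of the band-limited analytic signals.
#' With \code{orthogonalize = TRUE}, each signal's component orthogonal to the
#' other (Im(Y conj(X) / |X|)) replaces the raw envelope, removing shared
#' zero-phase signal; the result is symmetrized by averaging both directions.
#'
#' @param x,y equal-length signals.
#' @param fs sampling rate, Hz.
#' @param band frequency band, Hz.
#' @param orthogonalize remove the zero-lag shared component first.
#' @return Pearson correlation of log power envelopes, in [-1, 1].
#' @export
power_correlation_pair <- function(x, y, fs, band = c(4, 10),
                                   orthogonalize = FALSE) {
  ax <- analytic_signal(bandpass_filter(x, fs, band))
  ay <- analytic_signal(bandpass_filter(y, fs, band))
  trim <- as.integer(fs)
  keep <- (trim + 1):(length(x) - trim)
  ax <- ax[keep]; ay <- ay[keep]
  logpow <- function(a) log(pmax(Mod(a)^2, .Machine$double.xmin))
  if (!orthogonalize) {
    if (stats::sd(logpow(ax)) == 0 || stats::sd(logpow(ay)) == 0)
      stop("zero envelope variance")
    return(stats::cor(logpow(ax), logpow(ay)))
  }
  y_orth <- Im(ay * Conj(ax) / pmax(Mod(ax), .Machine$double.xmin))
  x_orth <- Im(ax * Conj(ay) / pmax(Mod(ay), .Machine$double.xmin))
  safe_cor <- function(a, b) {
    # a fully orthogonalized-away signal has no envelope left to correlate
    if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(0)
    stats::cor(a, b)
  }
  r1 <- safe_cor(logpow(ax), log(pmax(y_orth^2, .Machine$double.xmin)))
  r2 <- safe_cor(logpow(ay), log(pmax(x_orth^2, .Machine$double.xmin)))
  (r1 + r2) / 2
}

#' Per-epoch connectivity track for a channel pair
#'
#' Scores one connectivity metric in every scoring epoch, yielding a track
#' aligned with the hypnogram (and with 30 s slope tracks).
#'
#' @param rec a \code{\link{recording}}.
#' @param cha,chb channel indices of the pair.
#' @param metric one of \code{"coherence"}, \code{"plv"}, \code{"iplv"},
#'   \code{"power_corr"}, \code{"power_corr_ortho"}.
#' @param band frequency band, Hz.
#' @param epoch_sec epoch length, s.
#' @return numeric vector, one value per full epoch (NA where a metric
#'   fails).
#' @export
connectivity_track <- function(rec, cha, chb,
                               metric = c("coherence", "plv", "iplv",
                                          "power_corr", "power_corr_ortho"),
                               band = c(4, 10), epoch_sec = 30) {
  metric <- match.arg(metric)
  fs <- rec$fs
  nep <- as.integer(round(epoch_sec * fs))
  n_epochs <- ncol(rec$data) %/% nep
  vapply(seq_len(n_epochs), function(e) {
    idx <- (e - 1L) * nep + seq_len(nep)
    x <- rec$data[cha, idx]; y <- rec$data[chb, idx]
    tryCatch(switch(metric,
      coherence = coherence_pair(x, y, fs, band),
      plv = phase_locking_pair(x, y, fs, band)$plv,
      iplv = phase_locking_pair(x, y, fs, band)$iplv,
      power_corr = power_correlation_pair(x, y, fs, band),
      power_corr_ortho = power_correlation_pair(x, y, fs, band,
                                                orthogonalize = TRUE)),
      error = function(e) NA_real_)
  }, 0)
}

#' Rank state-tracking metrics by hypnogram mutual information
#'
#' Discretizes every epoch-aligned track (slope and connectivity metrics
#' alike) into 5 equal-width bins and computes its MI with the stage
#' sequence, returning a ranked table.
#'
#' @param tracks named list of numeric per-epoch tracks.
#' @param hyp a \code{\link{hypnogram}}; tracks must have one value per epoch.
#' @param n_bins discretization bins.
#' @return data.frame (metric, mi_bits) sorted by decreasing MI.
#' @export
compare_tracking <- function(tracks, hyp, n_bins = 5) {
  n <- length(hyp$labels)
  mi <- vapply(names(tracks), function(nm) {
    v <- tracks[[nm]]
    if (length(v) != n) stop("track '", nm, "' is not epoch-aligned")
    ok <- !is.na(v)
    mutual_information(discretize_values(v[ok], n_bins), hyp$labels[ok])
  }, 0)
  out <- data.frame(metric = names(tracks), mi_bits = unname(mi),
                    stringsAsFactors = FALSE)
  out[order(-out$mi_bits), ]
}
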