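# Aperiodic (1/f) slope estimators.
#
# The central quantity of the package: the slope of a straight-line fit to
# the power spectrum in log-log space, by default over 30-45 Hz. Alternative
# estimators (robust regression, aperiodic-model decomposition with Gaussian
# peak removal, IRASA fractal separation) are provided as controls; all agree
# on peak-free spectra.

slope_estimate <- function(slope, intercept, r_squared, band, method) {
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared, band = band, method = method),
            class = "slope_estimate")
}

#' @export
print.slope_estimate <- function(x, ...) {
  cat(sprintf("<slope_estimate> slope %.3f (R2 %.3f), %g-%g Hz, %s\n",
              x$slope, x$r_squared, x$band[1], x$band[2], x$method))
  invisible(x)
}

band_points <- function(freqs, power, band) {
  sel <- freqs >= band[1] & freqs <= band[2]
  if (sum(sel) < 3) stop("need at least 3 grid points inside the fit band")
  list(f = freqs[sel], p = power[sel])
}

#' Linear log-log slope fit
#'
#' Ordinary least squares of log10 power on log10 frequency over the grid
#' points inside the band (endpoints inclusive: on the canonical 0.5 Hz grid
#' the 30-45 Hz band contains 31 points). The slope is invariant to the log
#' base and to multiplicative rescaling of the signal; the intercept is the
#' log10 power extrapolated to log10 f = 0.
#'
#' @param freqs frequency grid, Hz.
#' @param power power values (one channel), all positive inside the band.
#' @param band length-2 numeric fit band, Hz.
#' @return a \code{slope_estimate}.
#' @export
fit_slope_linear <- function(freqs, power, band = c(30, 45)) {
  bp <- band_points(freqs, power, band)
  if (any(bp$p <= 0)) stop("non-positive power inside the fit band")
  lx <- log10(bp$f); ly <- log10(bp$p)
  fit <- stats::lm.fit(cbind(1, lx), ly)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  slope_estimate(unname(fit$coefficients[2]), unname(fit$coefficients[1]),
                 max(0, min(1, r2)), band, "linear")
}

#' Robust log-log slope fit
#'
#' Iteratively reweighted least squares with Tukey bisquare weights
#' (tuning constant 4.685), as in robust-regression slope controls.
#' On outlier-free spectra it coincides with the linear fit.
#'
#' @inheritParams fit_slope_linear
#' @param maxit maximum IWLS iterations.
#' @return a \code{slope_estimate}.
#' @export
fit_slope_robust <- function(freqs, power, band = c(30, 45), maxit = 50) {
  bp <- band_points(freqs, power, band)
  if (any(bp$p <= 0)) stop("non-positive power inside the fit band")
  lx <- log10(bp$f); ly <- log10(bp$p)
  fit <- suppressWarnings(
    MASS::rlm(ly ~ lx, psi = MASS::psi.bisquare, c = 4.685, maxit = maxit))
  if (!fit$converged) stop("robust slope fit did not converge")
  res <- ly - stats::fitted(fit)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1
  slope_estimate(unname(stats::coef(fit)[2]), unname(stats::coef(fit)[1]),
                 max(0, min(1, r2)), band, "robust")
}

# Gaussian evaluated on a log-frequency axis.
gauss_lf <- function(lf, center, height, width) {
  height * exp(-(lf - center)^2 / (2 * width^2))
}

#' Aperiodic-model slope fit with Gaussian peak removal
#'
#' Decomposes a spectrum into an aperiodic straight line (in log-log space,
#' no knee by default) and a set of Gaussian oscillatory peaks. The aperiodic
#' component is first fit robustly; residual peaks exceeding
#' \code{peak_threshold_sd} residual standard deviations are modelled as
#' Gaussians (on the log-frequency axis) and subtracted, iterating until the
#' noise floor is reached or \code{max_peaks} is hit; the aperiodic line is
#' then refit on the peak-removed spectrum.
#'
#' @inheritParams fit_slope_linear
#' @param max_peaks maximum number of Gaussian peaks to remove.
#' @param peak_threshold_sd residual threshold in SD units for declaring a
#'   peak ("noise floor").
#' @return list with \code{estimate} (a \code{slope_estimate}, method
#'   \code{"aperiodic_model"}) and \code{peaks} (data.frame: center_hz,
#'   height_log10, width_log10f).
#' @export
fit_aperiodic_model <- function(freqs, power, band = c(1, 45), max_peaks = 6,
                                peak_threshold_sd = 2) {
  if (diff(band) < 5) stop("aperiodic-model fit needs a band at least 5 Hz wide")
  bp <- band_points(freqs, power, band)
  if (any(bp$p <= 0)) stop("non-positive power inside the fit band")
  lf <- log10(bp$f); ly <- log10(bp$p)
  peak_model <- numeric(length(ly))
  peaks <- data.frame(center_hz = numeric(0), height_log10 = numeric(0),
                      width_log10f = numeric(0))
  warned <- FALSE
  for (it in seq_len(max_peaks + 1L)) {
    ap <- suppressWarnings(
      MASS::rlm((ly - peak_model) ~ lf, psi = MASS::psi.bisquare, maxit = 50))
    res <- ly - peak_model - stats::fitted(ap)
    # numerical floor (0.01 log10 units ~ 2% power) keeps rounding noise on
    # exact power laws from masquerading as peaks
    thr <- max(peak_threshold_sd * stats::sd(res), 0.01)
    i_max <- which.max(res)
    if (res[i_max] <= thr) break
    if (nrow(peaks) >= max_peaks) {
      warning("more than 'max_peaks' candidate peaks; stopping peak removal")
      warned <- TRUE
      break
    }
    # initial guesses from the residual shape
    h0 <- res[i_max]; c0 <- lf[i_max]
    above <- res >= h0 / 2
    # contiguous half-height run around the maximum
    l <- i_max; while (l > 1L && above[l - 1L]) l <- l - 1L
    r <- i_max; while (r < length(res) && above[r + 1L]) r <- r + 1L
    w0 <- max((lf[r] - lf[l]) / 2.355, diff(range(lf)) / 100)
    g <- tryCatch(suppressWarnings({
      ft <- stats::nls(res ~ gauss_lf(lf, c, h, w),
                       start = list(c = c0, h = h0, w = w0),
                       control = stats::nls.control(warnOnly = TRUE))
      as.list(stats::coef(ft))
    }), error = function(e) list(c = c0, h = h0, w = w0))
    if (g$h <= 0 || g$w <= 0) g <- list(c = c0, h = h0, w = w0)
    peak_model <- peak_model + gauss_lf(lf, g$c, g$h, g$w)
    peaks <- rbind(peaks, data.frame(center_hz = 10^g$c, height_log10 = g$h,
                                     width_log10f = g$w))
  }
  final <- stats::lm.fit(cbind(1, lf), ly - peak_model)
  res <- final$residuals
  ss_tot <- sum((ly - peak_model - mean(ly - peak_model))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1
  list(estimate = slope_estimate(unname(final$coefficients[2]),
                                 unname(final$coefficients[1]),
                                 max(0, min(1, r2)), band, "aperiodic_model"),
       peaks = peaks)
}

#' IRASA fractal/oscillatory spectral separation
#'
#' Irregular-resampling auto-spectral analysis: for each resampling factor h
#' the signal is resampled by h and by 1/h and the geometric mean of the two
#' spectra taken; oscillatory peaks shift with h while the scale-free fractal
#' component is invariant, so the median across factors isolates the fractal
#' spectrum. The oscillatory residual is the original minus the fractal PSD.
#'
#' @param x signal segment (at least 10 s recommended for low-frequency fits).
#' @param fs sampling rate, Hz.
#' @param h_set resampling factors, all > 1 (1/h applied implicitly).
#' @param win_sec Welch window length used for the underlying spectra, s.
#' @param fmax highest frequency returned, Hz.
#' @return list with \code{freqs}, \code{fractal}, \code{oscillatory},
#'   \code{original} power densities.
#' @export
irasa_fractal_psd <- function(x, fs, h_set = seq(1.1, 1.9, by = 0.05),
                              win_sec = 10, fmax = 45) {
  if (any(h_set <= 1)) stop("'h_set' factors must all exceed 1")
  n <- length(x)
  m <- floor(n / max(h_set)) - 1L
  welch_psd <- function(y, fs_y, nwin) {
    w <- 0.5 * (1 - cos(2 * pi * (0:(nwin - 1L)) / (nwin - 1L)))
    w <- w / sqrt(sum(w^2))
    starts <- seq(1L, length(y) - nwin + 1L, by = max(1L, nwin %/% 2L))
    nf <- floor(nwin / 2) + 1L
    acc <- numeric(nf)
    for (s in starts) {
      seg <- demean_detrend(y[s + seq_len(nwin) - 1L])
      acc <- acc + tapered_psd(seg, w, fs_y)
    }
    acc / length(starts)
  }
  nwin <- min(as.integer(round(win_sec * fs)), m)
  nf <- floor(nwin / 2) + 1L
  f <- (0:(nf - 1L)) * fs / nwin
  t_orig <- seq_len(n)
  frac_h <- matrix(NA_real_, length(h_set), nf)
  for (i in seq_along(h_set)) {
    h <- h_set[i]
    # upsample: evaluate at stride 1/h (spectrum compressed by h)
    up <- stats::spline(t_orig, x, xout = 1 + (0:(m - 1L)) / h)$y
    # downsample: anti-alias low-pass then evaluate at stride h
    lp <- signal::butter(4, min(0.9 / h, 0.99))
    xf <- signal::filtfilt(lp, x)
    dn <- stats::spline(t_orig, xf, xout = 1 + (0:(m - 1L)) * h)$y
    s_up <- welch_psd(up, fs, nwin)
    s_dn <- welch_psd(dn, fs, nwin)
    frac_h[i, ] <- sqrt(s_up * s_dn)
  }
  fractal <- apply(frac_h, 2, stats::median)
  orig <- welch_psd(x[seq_len(m)], fs, nwin)
  keep <- f <= fmax
  list(freqs = f[keep], fractal = fractal[keep],
       oscillatory = (orig - fractal)[keep], original = orig[keep])
}

#' Time-resolved spectral slope
#'
#' Per-segment multitaper spectra (taper count from the 2TW-1 rule) followed
#' by a per-segment slope fit, yielding one slope per segment and channel.
#' Failed fits propagate as NA for that segment, never aborting the track.
#'
#' @param rec a \code{\link{recording}}.
#' @param segment_sec segment length, s (30 for sleep, 10 for anesthesia).
#' @param band fit band, Hz.
#' @param method slope estimator: \code{"linear"} or \code{"robust"}.
#' @param psd_method spectral estimator passed to \code{\link{compute_psd}}.
#' @param halfbandwidth multitaper smoothing halfwidth, Hz.
#' @param channels channel indices to track (default: all non-EMG channels;
#'   EMG channels can be tracked explicitly for the muscle-tone covariate).
#' @return object of class \code{"slope_track"}: \code{times} (segment start
#'   times, s), \code{slopes} and \code{r_squared} (segments x channels),
#'   \code{band}, \code{method}, \code{segment_sec}, \code{channel_labels}.
#' @export
time_resolved_slope <- function(rec, segment_sec = 30, band = c(30, 45),
                                method = c("linear", "robust"),
                                psd_method = "multitaper", halfbandwidth = 0.5,
                                channels = NULL) {
  method <- match.arg(method)
  if (is.null(channels)) channels <- seq_len(nrow(rec$data))
  psd <- compute_psd(rec, psd_method, segment_sec = segment_sec,
                     halfbandwidth = halfbandwidth,
                     fmax = min(45, rec$fs / 2),
                     fstep = min(0.5, 1 / segment_sec))
  n_seg <- dim(psd$per_segment)[1]
  if (n_seg < 2) stop("recording must span at least 2 segments")
  fitter <- if (method == "linear") fit_slope_linear else fit_slope_robust
  slopes <- matrix(NA_real_, n_seg, length(channels))
  r2 <- matrix(NA_real_, n_seg, length(channels))
  for (s in seq_len(n_seg)) {
    for (j in seq_along(channels)) {
      est <- tryCatch(fitter(psd$freqs, psd$per_segment[s, channels[j], ], band),
                      error = function(e) NULL)
      if (!is.null(est)) { slopes[s, j] <- est$slope; r2[s, j] <- est$r_squared }
    }
  }
  structure(list(times = (seq_len(n_seg) - 1L) * segment_sec,
                 slopes = slopes, r_squared = r2, band = band,
                 method = method, segment_sec = segment_sec,
                 channel_labels = rec$channel_labels[channels]),
            class = "slope_track")
}

#' @export
print.slope_track <- function(x, ...) {
  cat(sprintf("<slope_track> %d segments x %d channel(s), %g s segments, %g-%g Hz (%s)\n",
              nrow(x$slopes), ncol(x$slopes), x$segment_sec,
              x$band[1], x$band[2], x$method))
  invisible(x)
}

#' Candidate fit bands for the parameter scan
#'
#' Builds the two published scan families: bands of +/- 10 Hz around a set of
#' center frequencies, and bands starting at a fixed low edge with increasing
#' length.
#'
#' @param centers center frequencies, Hz (each yields [c-10, c+10]).
#' @param lengths fit lengths, Hz (each yields [start, start+length]).
#' @param halfwidth halfwidth for center-based bands, Hz.
#' @param start low edge for length-based bands, Hz.
#' @return list of length-2 numeric bands.
#' @export
scan_bands <- function(centers = NULL, lengths = NULL, halfwidth = 10,
                       start = 30) {
  c(lapply(centers, function(c0) c(c0 - halfwidth, c0 + halfwidth)),
    lapply(lengths, function(L) c(start, start + L)))
}

#' Scan fit bands by hypnogram mutual information
#'
#' Recomputes the time-resolved slope for each candidate band from one shared
#' per-segment spectral decomposition, aligns each track to the hypnogram and
#' scores it by the mutual information between the 5-bin discretized slope and
#' the stage sequence. Returns the full ranking.
#'
#' @param rec a \code{\link{recording}}.
#' @param hyp a \code{\link{hypnogram}}.
#' @param bands list of length-2 numeric bands (see \code{\link{scan_bands}}).
#' @param channel channel index scored.
#' @param segment_sec segment length, s.
#' @param n_bins slope discretization bins for MI.
#' @return data.frame (band_lo, band_hi, mi_bits) sorted by decreasing MI,
#'   with the per-band slope tracks attached as attribute \code{"tracks"}.
#' @export
slope_parameter_scan <- function(rec, hyp, bands, channel = 1,
                                 segment_sec = 30, n_bins = 5) {
  fmax_need <- max(vapply(bands, max, 0))
  if (fmax_need > rec$fs / 2) stop("a scan band exceeds the Nyquist frequency")
  psd <- compute_psd(rec, "multitaper", segment_sec = segment_sec,
                     fmax = fmax_need, fstep = min(0.5, 1 / segment_sec))
  n_seg <- dim(psd$per_segment)[1]
  tracks <- matrix(NA_real_, n_seg, length(bands))
  mi <- numeric(length(bands))
  for (b in seq_along(bands)) {
    for (s in seq_len(n_seg)) {
      est <- tryCatch(
        fit_slope_linear(psd$freqs, psd$per_segment[s, channel, ], bands[[b]]),
        error = function(e) NULL)
      if (!is.null(est)) tracks[s, b] <- est$slope
    }
    tr <- structure(list(times = (seq_len(n_seg) - 1L) * segment_sec,
                         slopes = tracks[, b, drop = FALSE],
                         segment_sec = segment_sec),
                    class = "slope_track")
    al <- align_to_hypnogram(tr, hyp)
    mi[b] <- mutual_information(discretize_values(al$slope, n_bins), al$stage)
  }
  out <- data.frame(band_lo = vapply(bands, `[`, 0, 1),
                    band_hi = vapply(bands, `[`, 0, 2),
                    mi_bits = mi)
  out <- out[order(-out$mi_bits), ]
  attr(out, "tracks") <- tracks
  out
}
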