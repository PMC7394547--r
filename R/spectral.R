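# Spectral estimation.
#
# Multitaper estimation with discrete prolate spheroidal (Slepian) tapers is
# the work-horse: K orthogonal tapers concentrated in a +/- W halfbandwidth
# are applied to each segment and the tapered periodograms averaged, trading
# spectral resolution for variance reduction. Single-taper (Hann), raw
# periodogram and Welch (single Hamming window per segment) estimators are
# provided for the signal-to-noise comparison between methods.

.taper_cache <- new.env(parent = emptyenv())

# Slepian tapers via the symmetric tridiagonal eigenproblem.  For long
# windows the tapers are computed on a 1024-point base grid and interpolated
# by natural splines (they are smooth, with at most K half-lobes across the
# window), then renormalized to unit energy.
dpss_tapers <- function(n, nw, k, base_n = 1024L) {
  key <- paste(n, nw, k, sep = "_")
  hit <- .taper_cache[[key]]
  if (!is.null(hit)) return(hit)
  direct <- function(nn, w) {
    t0 <- 0:(nn - 1L)
    d <- ((nn - 1 - 2 * t0) / 2)^2 * cos(2 * pi * w)
    e <- (1:(nn - 1L)) * (nn - (1:(nn - 1L))) / 2
    A <- matrix(0, nn, nn)
    diag(A) <- d
    A[cbind(2:nn, 1:(nn - 1L))] <- e
    A[cbind(1:(nn - 1L), 2:nn)] <- e
    ev <- eigen(A, symmetric = TRUE)
    v <- ev$vectors[, seq_len(k), drop = FALSE]
    sweep(v, 2, sqrt(colSums(v^2)), "/")
  }
  w <- nw / n
  if (n <= 2048L) {
    v <- direct(n, w)
  } else {
    vb <- direct(base_n, nw / base_n)   # same time-bandwidth product
    xb <- seq(0, 1, length.out = base_n)
    xn <- seq(0, 1, length.out = n)
    v <- apply(vb, 2, function(col) stats::spline(xb, col, xout = xn)$y)
    v <- sweep(v, 2, sqrt(colSums(v^2)), "/")
  }
  attr(v, "concentration") <- taper_concentration(v, w)
  .taper_cache[[key]] <- v
  v
}

# Fraction of each taper's spectral energy inside the +/- W design band,
# evaluated on a finely zero-padded FFT grid. 1 - concentration is the
# taper's broadband leakage fraction.
taper_concentration <- function(v, w) {
  n <- nrow(v)
  nfft <- 2^ceiling(log2(8 * n))
  fgrid <- (0:(nfft - 1L)) / nfft
  fgrid <- pmin(fgrid, 1 - fgrid)
  inband <- fgrid <= w + .Machine$double.eps
  apply(v, 2, function(col) {
    p <- Mod(stats::fft(c(col, numeric(nfft - n))))^2
    sum(p[inband]) / sum(p)
  })
}

#' Number of Slepian tapers for a segment length and smoothing halfwidth
#'
#' The taper count follows directly from the time-bandwidth product:
#' K = 2 T W - 1 (floored when non-integer), with T the segment length in
#' seconds and W the one-sided frequency-smoothing halfwidth in Hz. A 30 s
#' segment with +/- 0.5 Hz smoothing yields 29 tapers; a 10 s segment yields 9.
#'
#' @param segment_sec segment length T, seconds.
#' @param halfbandwidth smoothing halfwidth W, Hz.
#' @return integer taper count K >= 1.
#' @export
dpss_taper_count <- function(segment_sec, halfbandwidth) {
  stopifnot_scalar(segment_sec, "segment_sec")
  stopifnot_scalar(halfbandwidth, "halfbandwidth")
  if (segment_sec <= 0 || halfbandwidth <= 0)
    stop("segment length and halfbandwidth must be positive")
  k <- floor(2 * segment_sec * halfbandwidth - 1 + 1e-9)
  if (k < 1) stop("time-bandwidth product too small: 2*T*W - 1 < 1")
  as.integer(k)
}

demean_detrend <- function(x) {
  n <- length(x)
  t <- seq_len(n)
  stats::lm.fit(cbind(1, t), x)$residuals
}

# One-sided PSD of a detrended segment under a unit-energy taper.
tapered_psd <- function(x, taper, fs) {
  n <- length(x)
  X <- stats::fft(x * taper)
  nf <- floor(n / 2) + 1L
  p <- Mod(X[seq_len(nf)])^2 / fs
  scale2 <- rep(2, nf); scale2[1] <- 1
  if (n %% 2 == 0) scale2[nf] <- 1
  p * scale2
}

#' Power spectral density of a recording
#'
#' Cuts each channel into non-overlapping segments, demeans and linearly
#' detrends each, estimates the one-sided PSD per segment with the chosen
#' method, and averages across segments. The spectrum is returned on the
#' requested frequency grid (each requested frequency mapped to the nearest
#' native FFT bin, which is exact when \code{segment_sec*fstep} is an integer).
#' Segments containing NaN are excluded from the average.
#'
#' @param rec a \code{\link{recording}}.
#' @param method one of \code{"multitaper"}, \code{"hanning"},
#'   \code{"periodogram"}, \code{"welch"}.
#' @param segment_sec segment length, seconds (30 for sleep, 10 for anesthesia
#'   by convention).
#' @param halfbandwidth multitaper smoothing halfwidth, Hz.
#' @param fmin,fmax,fstep requested frequency grid, Hz.
#' @param taper_leak_tol multitaper only: tapers whose broadband leakage
#'   fraction (one minus the in-band energy concentration) exceeds this
#'   tolerance are excluded from the average. The taper-count rule fixes the
#'   nominal K; the last Slepian orders of a large time-bandwidth family leak
#'   a non-negligible fraction of total signal power across the spectrum,
#'   which floors the 30-45 Hz range when the spectrum spans many decades
#'   (steep 1/f). Set to \code{Inf} to average all K tapers.
#' @return object of class \code{"power_spectrum"}: \code{freqs},
#'   \code{power} (channels x freqs, density units), \code{per_segment}
#'   (segments x channels x freqs), \code{method}, \code{segment_sec},
#'   \code{n_tapers} (nominal K from the rule), \code{n_tapers_used},
#'   \code{channel_labels}.
#' @export
compute_psd <- function(rec, method = c("multitaper", "hanning", "periodogram",
                                        "welch"),
                        segment_sec = 30, halfbandwidth = 0.5,
                        fmin = 0.5, fmax = 45, fstep = 0.5,
                        taper_leak_tol = 1e-5) {
  method <- match.arg(method)
  fs <- rec$fs
  if (fmax > fs / 2) stop("requested grid extends beyond Nyquist")
  nseg <- as.integer(round(segment_sec * fs))
  if (nseg < 2) stop("segment too short")
  n <- ncol(rec$data)
  n_segments <- n %/% nseg
  if (n_segments < 1) stop("recording shorter than one segment")
  k <- if (method == "multitaper")
    dpss_taper_count(segment_sec, halfbandwidth) else 1L
  tapers <- switch(method,
    multitaper = {
      v <- dpss_tapers(nseg, segment_sec * halfbandwidth, k)
      conc <- attr(v, "concentration")
      keep <- which(1 - conc <= taper_leak_tol)
      if (!length(keep)) keep <- 1L
      v[, keep, drop = FALSE]
    },
    hanning = {
      w <- 0.5 * (1 - cos(2 * pi * (0:(nseg - 1L)) / (nseg - 1L)))
      matrix(w / sqrt(sum(w^2)), ncol = 1)
    },
    periodogram = matrix(rep(1 / sqrt(nseg), nseg), ncol = 1),
    welch = {
      w <- 0.54 - 0.46 * cos(2 * pi * (0:(nseg - 1L)) / (nseg - 1L))
      matrix(w / sqrt(sum(w^2)), ncol = 1)
    })
  nf <- floor(nseg / 2) + 1L
  f_native <- (0:(nf - 1L)) * fs / nseg
  freqs <- seq(fmin, fmax, by = fstep)
  bin <- vapply(freqs, function(f) which.min(abs(f_native - f)), 0L)
  nch <- nrow(rec$data)
  per_seg <- array(NA_real_, dim = c(n_segments, nch, length(freqs)))
  for (s in seq_len(n_segments)) {
    idx <- (s - 1L) * nseg + seq_len(nseg)
    for (ch in seq_len(nch)) {
      x <- rec$data[ch, idx]
      if (anyNA(x)) next
      x <- demean_detrend(x)
      acc <- numeric(nf)
      for (j in seq_len(ncol(tapers)))
        acc <- acc + tapered_psd(x, tapers[, j], fs)
      per_seg[s, ch, ] <- (acc / ncol(tapers))[bin]
    }
  }
  ok <- !apply(per_seg, 1, function(sl) anyNA(sl))
  if (!any(ok)) stop("all segments contain NaN")
  pw <- apply(per_seg[ok, , , drop = FALSE], c(2, 3), mean)
  structure(list(freqs = freqs, power = pw, per_segment = per_seg,
                 method = method, segment_sec = segment_sec,
                 n_tapers = k, n_tapers_used = ncol(tapers),
                 channel_labels = rec$channel_labels),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %s, %d channel(s), %g-%g Hz (%d bins), %g s segments",
              x$method, nrow(x$power), min(x$freqs), max(x$freqs),
              length(x$freqs), x$segment_sec))
  if (x$method == "multitaper") cat(sprintf(", %d tapers", x$n_tapers))
  cat("\n")
  invisible(x)
}

#' Across-segment signal-to-noise ratio of a spectral estimate
#'
#' SNR(f, ch) = mean over segments / standard deviation over segments of the
#' per-segment power. Frequencies with zero across-segment SD are flagged as
#' infinite (with a warning), never silently dropped.
#'
#' @param psd a \code{power_spectrum} with at least two valid segments.
#' @return channels x freqs matrix of SNR values.
#' @export
compute_snr <- function(psd) {
  ps <- psd$per_segment
  ok <- !apply(ps, 1, function(sl) anyNA(sl))
  if (sum(ok) < 2) stop("need at least two valid segments for SNR")
  ps <- ps[ok, , , drop = FALSE]
  m <- apply(ps, c(2, 3), mean)
  s <- apply(ps, c(2, 3), stats::sd)
  snr <- m / s
  if (any(s == 0)) {
    warning("zero across-segment SD at some bins; SNR flagged as Inf")
    snr[s == 0] <- Inf
  }
  dimnames(snr) <- list(psd$channel_labels, NULL)
  snr
}

#' Mean band power per channel
#'
#' Mean power over the grid points falling inside the band (bounds inclusive).
#' With a baseline spectrum, returns the relative change
#' (power - baseline)/baseline per channel.
#'
#' @param psd a \code{power_spectrum}.
#' @param band length-2 numeric, Hz.
#' @param baseline optional \code{power_spectrum} on the same grid.
#' @return numeric vector, one value per channel.
#' @export
band_power <- function(psd, band, baseline = NULL) {
  sel <- psd$freqs >= band[1] & psd$freqs <= band[2]
  if (!any(sel)) stop("band does not intersect the frequency grid")
  p <- rowMeans(psd$power[, sel, drop = FALSE])
  if (!is.null(baseline)) {
    if (!isTRUE(all.equal(psd$freqs, baseline$freqs)))
      stop("baseline must share the frequency grid")
    b <- rowMeans(baseline$power[, sel, drop = FALSE])
    p <- (p - b) / b
  }
  stats::setNames(p, psd$channel_labels)
}

#' Sliding-window spectra around events
#'
#' Event-locked time-frequency decomposition: 0.5 s windows stepping 0.25 s
#' across each epoch, one Slepian taper with +/- 2 Hz smoothing halfwidth per
#' window (the taper count rule gives K = 1 at this time-bandwidth product).
#' For the canonical 5 s (+/- 2.5 s) slow-wave epoch this yields 19 windows
#' with centers -2.25 ... +2.25 s relative to the epoch center.
#'
#' @param epochs events x samples matrix (each row one event-locked epoch).
#' @param fs sampling rate, Hz.
#' @param win_sec,step_sec window length and step, seconds.
#' @param halfbandwidth taper smoothing halfwidth, Hz.
#' @return list with \code{power} (events x windows x freqs),
#'   \code{freqs} (Hz), and \code{centers} (window centers in seconds relative
#'   to the epoch center).
#' @export
event_tfr <- function(epochs, fs, win_sec = 0.5, step_sec = 0.25,
                      halfbandwidth = 2) {
  if (is.vector(epochs)) epochs <- matrix(epochs, nrow = 1L)
  n <- ncol(epochs)
  nwin <- as.integer(round(win_sec * fs))
  nstep <- as.integer(round(step_sec * fs))
  if (n < nwin) stop("epoch shorter than one window")
  k <- dpss_taper_count(win_sec, halfbandwidth)
  tapers <- dpss_tapers(nwin, win_sec * halfbandwidth, k)
  starts <- seq(1L, n - nwin + 1L, by = nstep)
  centers <- (starts - 1L + nwin / 2) / fs - n / (2 * fs)
  nf <- floor(nwin / 2) + 1L
  freqs <- (0:(nf - 1L)) * fs / nwin
  out <- array(NA_real_, dim = c(nrow(epochs), length(starts), nf))
  for (ev in seq_len(nrow(epochs))) {
    for (w in seq_along(starts)) {
      x <- epochs[ev, starts[w] + seq_len(nwin) - 1L]
      if (anyNA(x)) next
      x <- demean_detrend(x)
      acc <- numeric(nf)
      for (j in seq_len(ncol(tapers)))
        acc <- acc + tapered_psd(x, tapers[, j], fs)
      out[ev, w, ] <- acc / ncol(tapers)
    }
  }
  list(power = out, freqs = freqs, centers = centers)
}
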