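# Shared fixtures and independent oracles.

# Independent PSD oracle: tapered periodogram via stats::spec.pgram (base R),
# averaged over non-overlapping segments. Used to check the package's own
# spectral path without sharing code with it.
oracle_psd <- function(x, fs, segment_sec = 30) {
  nseg <- round(segment_sec * fs)
  n_segments <- length(x) %/% nseg
  acc <- NULL
  for (s in seq_len(n_segments)) {
    seg <- x[(s - 1) * nseg + seq_len(nseg)]
    # taper = 0.5 (full split cosine bell): enough sidelobe suppression for
    # spectra spanning many decades
    sp <- stats::spec.pgram(stats::ts(seg, frequency = fs), taper = 0.5,
                            detrend = TRUE, plot = FALSE)
    acc <- if (is.null(acc)) sp$spec else acc + sp$spec
  }
  list(freq = sp$freq, spec = acc / n_segments)
}

# Independent slope oracle: log-log OLS on an oracle PSD.
oracle_slope <- function(x, fs, band = c(30, 45), segment_sec = 30) {
  ps <- oracle_psd(x, fs, segment_sec)
  sel <- ps$freq >= band[1] & ps$freq <= band[2]
  unname(coef(stats::lm(log10(ps$spec[sel]) ~ log10(ps$freq[sel])))[2])
}

# Small two-state recording: W-like (-2) and REM-like (-4.5) slopes only,
# no oscillations/slow waves, used where a clean slope contrast is needed.
two_state_profiles <- function(s1 = -2, s2 = -4.5) {
  list(
    W = list(target_slope = s1, oscillations = list(),
             slow_wave_rate = 0, emg_level = 0.2),
    REM = list(target_slope = s2, oscillations = list(),
               slow_wave_rate = 0, emg_level = 0.05)
  )
}

make_recording <- function(x, fs = 200) recording(x, fs)

expect_within <- function(object, target, tol) {
  expect_lt(abs(object - target), tol)
}
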