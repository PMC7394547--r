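# Spectral estimation: taper rule, PSD methods, SNR, band power, event TFR.

test_that("taper-count rule reproduces the published settings", {
  expect_identical(dpss_taper_count(30, 0.5), 29L)
  expect_identical(dpss_taper_count(10, 0.5), 9L)
  expect_identical(dpss_taper_count(2, 0.5), 1L)
  expect_identical(dpss_taper_count(0.5, 2), 1L)   # event-locked windows
  expect_error(dpss_taper_count(0.5, 0.5), "too small")
  expect_error(dpss_taper_count(-1, 0.5), "positive")
})

test_that("taper count is monotone non-decreasing in both arguments", {
  for (T in c(2, 5, 10, 30)) {
    ks <- sapply(c(0.5, 1, 2, 4), function(W) dpss_taper_count(T, W))
    expect_true(all(diff(ks) >= 0))
  }
  for (W in c(0.5, 1, 2)) {
    ks <- sapply(c(2, 5, 10, 30), function(T) dpss_taper_count(T, W))
    expect_true(all(diff(ks) >= 0))
  }
})

test_that("Slepian tapers are orthonormal and spectrally concentrated", {
  v <- slopetrack:::dpss_tapers(1000, 4, 7)
  g <- crossprod(v)
  expect_lt(max(abs(g - diag(7))), 1e-6)
  conc <- attr(v, "concentration")
  expect_true(all(conc[1:3] > 1 - 1e-5))  # low orders: essentially leak-free
  expect_true(all(conc > 0.85))           # last order of a 2TW-1 family leaks ~10%
  expect_true(all(diff(conc) <= 1e-12))   # decreasing with taper order
  # interpolated long-window tapers keep orthonormality
  vl <- slopetrack:::dpss_tapers(6000, 15, 29)
  expect_lt(max(abs(diag(crossprod(vl)) - 1)), 1e-9)
})

test_that("all four PSD methods localize a pure sinusoid", {
  fs <- 200
  t <- (0:(fs * 60 - 1)) / fs
  rec <- recording(sin(2 * pi * 10 * t) + 0.01 * sin(2 * pi * 33 * t), fs)
  for (m in c("multitaper", "hanning", "periodogram", "welch")) {
    psd <- compute_psd(rec, m, segment_sec = 30)
    expect_equal(psd$freqs[which.max(psd$power[1, ])], 10,
                 tolerance = 1e-9, label = m)
  }
  expect_error(compute_psd(rec, "multitaper", fmax = 150), "Nyquist")
})

test_that("white-noise spectra are flat and scale with variance", {
  fs <- 200
  x <- gen_powerlaw_signal(fs * 300, fs, 0, seed = 11)
  psd <- compute_psd(recording(x, fs), "multitaper", segment_sec = 30)
  lo <- mean(psd$power[1, psd$freqs <= 20])
  hi <- mean(psd$power[1, psd$freqs >= 25])
  expect_within(lo / hi, 1, 0.05)
  # Parseval sanity: band power scales linearly with signal variance
  p1 <- band_power(psd, c(0.5, 45))
  psd4 <- compute_psd(recording(2 * x, fs), "multitaper", segment_sec = 30)
  expect_within(band_power(psd4, c(0.5, 45)) / p1, 4, 0.2)
})

test_that("multitaper recovers steep synthetic exponents through the full path", {
  fs <- 400
  for (target in c(-2, -4)) {
    fits <- sapply(1:3, function(sd) {
      x <- gen_powerlaw_signal(fs * 120, fs, target, seed = 20 + sd)
      psd <- compute_psd(recording(x, fs), "multitaper", segment_sec = 30)
      fit_slope_linear(psd$freqs, psd$power[1, ])$slope
    })
    expect_within(mean(fits), target, 0.15)
  }
})

test_that("PSD estimation is deterministic, channel-order invariant and NaN-aware", {
  fs <- 100
  x <- gen_powerlaw_signal(fs * 90, fs, -2, seed = 3)
  y <- gen_powerlaw_signal(fs * 90, fs, -3, seed = 4)
  r12 <- recording(rbind(x, y), fs, c("a", "b"))
  r21 <- recording(rbind(y, x), fs, c("b", "a"))
  p12 <- compute_psd(r12, "multitaper", segment_sec = 30)
  p21 <- compute_psd(r21, "multitaper", segment_sec = 30)
  expect_identical(p12$power[1, ], p21$power[2, ])
  expect_identical(p12$power, compute_psd(r12, "multitaper", segment_sec = 30)$power)
  # a NaN segment is excluded from the average, not propagated
  xna <- x; xna[1:10] <- NaN
  pna <- compute_psd(recording(xna, fs), "multitaper", segment_sec = 30)
  expect_true(all(is.na(pna$per_segment[1, 1, ])))
  expect_false(anyNA(pna$power))
  p_clean <- compute_psd(recording(x[-(1:(30 * fs))], fs), "multitaper",
                         segment_sec = 30)
  expect_equal(pna$power[1, ], p_clean$power[1, ], tolerance = 1e-12)
})

test_that("across-segment SNR follows its definition and flags zero SD", {
  # hand example: per-segment powers {2, 4} at every bin -> SNR = 3/sqrt(2)
  psd <- structure(list(
    freqs = c(1, 2), power = matrix(3, 1, 2),
    per_segment = array(rep(c(2, 4), each = 1, times = 2), c(2, 1, 2)),
    method = "multitaper", segment_sec = 1, n_tapers = 1,
    channel_labels = "a"), class = "power_spectrum")
  psd$per_segment[1, 1, ] <- 2; psd$per_segment[2, 1, ] <- 4
  expect_equal(unname(compute_snr(psd)[1, 1]), 3 / sqrt(2), tolerance = 1e-12)
  psd$per_segment[2, 1, ] <- 2
  expect_warning(snr0 <- compute_snr(psd), "Inf")
  expect_true(all(is.infinite(snr0)))
})

test_that("multitaper SNR beats single-window estimators on stationary 1/f", {
  fs <- 200
  x <- gen_powerlaw_signal(fs * 600, fs, -2, seed = 5)
  rec <- recording(x, fs)
  snr_mt <- compute_snr(compute_psd(rec, "multitaper", segment_sec = 30))
  snr_w <- compute_snr(compute_psd(rec, "welch", segment_sec = 30))
  expect_gt(mean(snr_mt > snr_w), 0.9)
})

test_that("band power averages the in-band grid points", {
  psd <- structure(list(
    freqs = seq(0.5, 45, 0.5),
    power = matrix(7, 1, 90), per_segment = NULL,
    method = "multitaper", segment_sec = 30, n_tapers = 29,
    channel_labels = "a"), class = "power_spectrum")
  expect_equal(unname(band_power(psd, c(4, 8))), 7)
  # "< 1.25 Hz" intersects the 0.5 Hz grid at exactly {0.5, 1.0}
  psd$power[1, ] <- seq_along(psd$freqs)
  expect_equal(unname(band_power(psd, c(0, 1.24))), mean(c(1, 2)))
  base <- psd
  expect_equal(unname(band_power(psd, c(4, 8), baseline = base)), 0)
  expect_error(band_power(psd, c(50, 60)), "intersect")
})

test_that("event TFR windowing matches the sliding-window design", {
  fs <- 200
  # 5 s epoch -> 19 windows centered -2.25 ... +2.25 s
  t <- (0:(5 * fs - 1)) / fs
  ep <- sin(2 * pi * 40 * t)
  tfr <- event_tfr(ep, fs)
  expect_identical(dim(tfr$power)[2], 19L)
  expect_equal(range(tfr$centers), c(-2.25, 2.25))
  # stationary tone: power at 40 Hz constant across windows within 5%
  i40 <- which.min(abs(tfr$freqs - 40))
  p40 <- tfr$power[1, , i40]
  expect_lt(diff(range(p40)) / mean(p40), 0.05)
  expect_error(event_tfr(ep[1:50], fs), "shorter")
})

test_that("event TFR tracks an amplitude-modulated envelope", {
  fs <- 200
  t <- (0:(5 * fs - 1)) / fs
  env <- 1 + 0.8 * sin(2 * pi * 0.4 * t)
  tfr <- event_tfr(env * sin(2 * pi * 40 * t), fs)
  i40 <- which.min(abs(tfr$freqs - 40))
  p <- tfr$power[1, , i40]
  env_at <- (1 + 0.8 * sin(2 * pi * 0.4 * (tfr$centers + 2.5)))^2
  expect_gt(cor(p, env_at, method = "spearman"), 0.9)
})
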