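# Slope estimators and the control-analysis machinery.

grid <- seq(0.5, 45, 0.5)

test_that("linear log-log fit is exact on power laws and flat spectra", {
  est <- fit_slope_linear(grid, grid^(-2))
  expect_equal(est$slope, -2, tolerance = 1e-12)
  expect_equal(est$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit_slope_linear(grid, rep(3, length(grid)))$slope, 0,
               tolerance = 1e-12)
  # intercept reproduces the power-law constant: power = 10 * f^-2
  est10 <- fit_slope_linear(grid, 10 * grid^(-2))
  expect_equal(est10$intercept, 1, tolerance = 1e-12)
  # small iid relative noise keeps the fit within +-0.05
  set.seed(1)
  noisy <- 10 * grid^(-3) * (1 + runif(length(grid), -0.05, 0.05))
  expect_within(fit_slope_linear(grid, noisy)$slope, -3, 0.05)
  expect_error(fit_slope_linear(grid, grid^(-2) - 1), "non-positive")
  expect_error(fit_slope_linear(c(30, 40), c(1, 1)), "3 grid points")
})

test_that("slope is invariant to log base and signal scaling", {
  p <- grid^(-2.5)
  s1 <- fit_slope_linear(grid, p)$slope
  s2 <- fit_slope_linear(grid, 1e6 * p)$slope       # multiplicative scale
  expect_lt(abs(s1 - s2), 1e-9)
  # natural-log fit agrees with the log10 fit
  sel <- grid >= 30 & grid <= 45
  s_ln <- unname(coef(lm(log(p[sel]) ~ log(grid[sel])))[2])
  expect_lt(abs(s1 - s_ln), 1e-9)
})

test_that("robust fit equals OLS on clean spectra and resists outliers", {
  p <- grid^(-3)
  expect_within(fit_slope_robust(grid, p)$slope,
                fit_slope_linear(grid, p)$slope, 1e-6)
  # one 10x outlier bin: bisquare fit stays closer to the truth
  p_out <- p; p_out[which(grid == 37)] <- 10 * p_out[which(grid == 37)]
  e_lin <- abs(fit_slope_linear(grid, p_out)$slope + 3)
  e_rob <- abs(fit_slope_robust(grid, p_out)$slope + 3)
  expect_lt(e_rob, e_lin)
})

test_that("robust and linear slopes are strongly correlated across spectra", {
  set.seed(7)
  slopes <- runif(100, -4.5, -1)
  fits <- t(sapply(slopes, function(s) {
    p <- grid^s * (1 + runif(length(grid), -0.3, 0.3))
    c(fit_slope_linear(grid, p)$slope, fit_slope_robust(grid, p)$slope)
  }))
  expect_gt(cor(fits[, 1], fits[, 2]), 0.95)
  expect_lt(max(abs(fits[, 1] - fits[, 2])), 0.25)
})

test_that("aperiodic-model fit separates peaks from the 1/f background", {
  # pure power law: no peaks, slope recovered
  res <- fit_aperiodic_model(grid, 2 * grid^(-2), band = c(1, 40))
  expect_identical(nrow(res$peaks), 0L)
  expect_within(res$estimate$slope, -2, 0.1)
  # power law + alpha bump: one peak near 10 Hz, aperiodic slope preserved
  lf <- log10(grid)
  bump <- 0.8 * exp(-(lf - 1)^2 / (2 * 0.05^2))     # centered at 10 Hz
  p <- 10^(log10(2 * grid^(-2)) + bump)
  res2 <- fit_aperiodic_model(grid, p, band = c(1, 40))
  expect_gte(nrow(res2$peaks), 1L)
  expect_within(res2$peaks$center_hz[1], 10, 1.5)
  expect_within(res2$estimate$slope, -2, 0.15)
  # peak-free high band: agreement with the plain linear fit
  res3 <- fit_aperiodic_model(grid, p, band = c(30, 45))
  expect_within(res3$estimate$slope,
                fit_slope_linear(grid, p, c(30, 45))$slope, 0.1)
  expect_error(fit_aperiodic_model(grid, p, band = c(30, 33)), "5 Hz")
})

test_that("estimator concordance holds on peak-free synthetic spectra", {
  set.seed(3)
  # noise spikes can exhaust the peak budget on some draws; that warning is
  # part of the contract and irrelevant to the slope concordance under test
  draws <- suppressWarnings(t(sapply(runif(100, -4, -1.5), function(s) {
    p <- grid^s * (1 + runif(length(grid), -0.1, 0.1))
    c(lin = fit_slope_linear(grid, p)$slope,
      rob = fit_slope_robust(grid, p)$slope,
      ap = fit_aperiodic_model(grid, p, band = c(30, 45))$estimate$slope)
  })))
  expect_gt(min(cor(draws)), 0.95)
  expect_lt(max(abs(draws[, "lin"] - draws[, "ap"])), 0.1)
})

test_that("IRASA isolates the fractal component from an oscillation", {
  fs <- 200
  x <- gen_powerlaw_signal(fs * 240, fs, -2, seed = 2)
  # pure power law: fractal close to the original estimate over 2-40 Hz
  ir <- irasa_fractal_psd(x, fs, win_sec = 4)
  sel <- ir$freqs >= 2 & ir$freqs <= 40
  expect_lt(stats::median(abs(ir$fractal[sel] / ir$original[sel] - 1)), 0.1)
  # a strong low-frequency oscillation (slow-delta range, where it has
  # leverage on a 1-20 Hz fit) distorts the raw fit but not the fractal fit
  tone <- gen_oscillation_burst(4, 5, 1, fs * 240, fs, seed = 3)
  ir2 <- irasa_fractal_psd(x + tone, fs, win_sec = 4)
  f_frac <- fit_slope_linear(ir2$freqs, pmax(ir2$fractal, 1e-12),
                             band = c(1, 20))$slope
  f_raw <- fit_slope_linear(ir2$freqs, ir2$original, band = c(1, 20))$slope
  expect_within(f_frac, -2, 0.2)
  expect_gt(abs(f_raw + 2), 0.3)
  # energy bookkeeping: the oscillatory residual integrates to roughly the
  # tone's variance (A^2/2)
  band <- ir2$freqs >= 2 & ir2$freqs <= 6
  df <- diff(ir2$freqs[1:2])
  expect_within(sum(ir2$oscillatory[band]) * df, var(tone), 0.5 * var(tone))
  expect_error(irasa_fractal_psd(x, fs, h_set = c(1, 1.5)), "exceed 1")
})

test_that("time-resolved slope tracks stationary and step-changing signals", {
  fs <- 200
  x <- gen_powerlaw_signal(fs * 600, fs, -2, seed = 4)
  tr <- time_resolved_slope(recording(x, fs))
  expect_within(mean(tr$slopes[, 1]), -2, 0.1)
  # per-30 s-fit spread: consistent with the multitaper estimator's own
  # noise floor (~0.32 SD at 23 concentrated tapers over 31 half-Hz bins)
  expect_lt(sd(tr$slopes[, 1]), 0.45)
  # concatenated -2 / -4 halves: clear step at the boundary
  y <- c(gen_powerlaw_signal(fs * 300, fs, -2, seed = 5),
         gen_powerlaw_signal(fs * 300, fs, -4, seed = 6))
  tr2 <- time_resolved_slope(recording(y, fs))
  first <- mean(tr2$slopes[1:10, 1]); second <- mean(tr2$slopes[11:20, 1])
  expect_within(first, -2, 0.3)
  expect_within(second, -4, 0.3)
  expect_error(time_resolved_slope(recording(x[1:(30 * fs)], fs)),
               "2 segments")
})

test_that("10 s and 30 s segment tracks correlate on state-varying data", {
  fs <- 200
  sim <- gen_recording(two_state_profiles(), hypnogram(rep(c("W", "REM"), 10)),
                       n_channels = 1, fs = fs, seed = 7)
  t30 <- time_resolved_slope(sim$recording, segment_sec = 30, channels = 1)
  t10 <- time_resolved_slope(sim$recording, segment_sec = 10, channels = 1)
  # average the 10 s track onto the 30 s grid
  agg <- colMeans(matrix(t10$slopes[, 1], nrow = 3))
  expect_gt(cor(agg, t30$slopes[, 1]), 0.8)
})

test_that("failed per-segment fits propagate as NA without aborting", {
  fs <- 100
  x <- gen_powerlaw_signal(fs * 90, fs, -2, seed = 8)
  x[(30 * fs + 1):(31 * fs)] <- NaN
  tr <- time_resolved_slope(recording(x, fs))
  expect_true(is.na(tr$slopes[2, 1]))
  expect_false(anyNA(tr$slopes[c(1, 3), 1]))
})

test_that("band scan ranks the discriminative band by mutual information", {
  fs <- 200
  # states differ ONLY inside 30-50 Hz: common 1/f background plus a
  # band-limited noise component whose amplitude depends on the state
  hyp <- hypnogram(rep(c("W", "REM"), 8))
  nep <- 30 * fs
  # frequency-domain construction: a common -2 power law everywhere except
  # 30-50 Hz, where the local exponent is state-dependent (pivot at 40 Hz so
  # edge discontinuities stay small)
  state_signal <- function(n, fs, s_band) {
    X <- stats::fft(rnorm(n))
    f <- pmin(0:(n - 1), n - (0:(n - 1))) * fs / n
    psd <- pmax(f, 1)^(-2)
    inb <- f >= 30 & f <= 50
    psd[inb] <- 40^(-2) * (f[inb] / 40)^s_band
    amp <- sqrt(psd); amp[1] <- 0
    Re(stats::fft(X * amp, inverse = TRUE)) / n
  }
  set.seed(9)
  x <- unlist(lapply(seq_along(hyp$labels), function(e)
    state_signal(nep, fs, if (hyp$labels[e] == "W") -1 else -3)))
  rec <- recording(x, fs)
  bands <- scan_bands(centers = c(20, 40, 60, 80), lengths = c(15, 40))
  scan <- slope_parameter_scan(rec, hyp, bands)
  expect_identical(nrow(scan), 6L)
  # the 30-45 Hz family must rank among the top 3
  top3 <- scan[1:3, c("band_lo", "band_hi")]
  expect_true(any(top3$band_lo == 30 & top3$band_hi == 45))
  # duplicate bands give identical MI; a single band degenerates cleanly
  dup <- slope_parameter_scan(rec, hyp, list(c(30, 45), c(30, 45)))
  expect_equal(dup$mi_bits[1], dup$mi_bits[2], tolerance = 1e-12)
  expect_error(slope_parameter_scan(rec, hyp, list(c(90, 120))), "Nyquist")
})
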