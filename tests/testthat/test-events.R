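# Slow-wave detection and event-locked slope dynamics.

# Recording with known injected ~1 s slow waves over a low background. The
# 0.8-1.25 Hz noise supplies the sub-threshold candidate population the
# percentile criterion needs (its zero-crossing rate is amplitude-invariant),
# while the injected waves fill the kept upper quartile; the injection rate is
# matched to the measured noise-candidate rate so recall and precision are
# simultaneously attainable.
sw_fixture <- function(minutes = 10, fs = 200, rate = 10, amp = 6, seed = 1) {
  n <- minutes * 60 * fs
  band_noise <- function(n, fs, lo, hi, seed) {
    set.seed(seed)
    X <- stats::fft(rnorm(n))
    f <- pmin(0:(n - 1), n - (0:(n - 1))) * fs / n
    X[f < lo | f > hi] <- 0
    x <- Re(stats::fft(X, inverse = TRUE)) / n
    x / sd(x)
  }
  bg <- 0.1 * gen_powerlaw_signal(n, fs, -2, seed = seed) +
    0.2 * band_noise(n, fs, 0.8, 1.25, seed + 1)
  sw <- gen_slow_waves(rate, amp, c(0.9, 1.1), n, fs, seed = seed + 100)
  list(rec = recording(bg + sw$signal, fs), truth = sw$trough_times)
}

test_that("high-frequency signals produce no slow-wave events", {
  fs <- 200
  t <- (0:(fs * 60 - 1)) / fs
  rec <- recording(sin(2 * pi * 40 * t) + 0.01 * rnorm(length(t)), fs)
  ev <- suppressWarnings(detect_slow_waves(rec))
  expect_identical(nrow(ev), 0L)
  # a genuinely crossing-free trace triggers the explicit warning
  flat <- recording(rep(c(1e-9, 2e-9), fs * 20), fs)
  expect_warning(detect_slow_waves(flat), "crossings|candidates")
})

test_that("detector recovers injected slow waves with high recall and precision", {
  fx <- sw_fixture()
  ev <- detect_slow_waves(fx$rec, hyp = hypnogram(rep("N3", 20)))
  match_tol <- 0.1
  hits <- sapply(fx$truth, function(tt) any(abs(ev$trough_time_s - tt) <= match_tol))
  recall <- mean(hits)
  precision <- mean(sapply(ev$trough_time_s, function(dt)
    any(abs(fx$truth - dt) <= match_tol)))
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
  expect_true(all(ev$state == "N3"))
})

test_that("detected events satisfy the duration and amplitude contract", {
  fx <- sw_fixture(seed = 7)
  ev <- detect_slow_waves(fx$rec)
  expect_true(all(ev$duration_s >= 0.8 & ev$duration_s <= 2))
  expect_true(all(ev$start_s < ev$trough_time_s))
  expect_true(all(ev$trough_time_s < ev$end_s))
  # non-overlap on the channel
  expect_true(all(ev$start_s[-1] >= ev$end_s[-nrow(ev)] - 1e-9))
  # raising the percentile never increases the count
  n75 <- nrow(ev)
  n90 <- nrow(detect_slow_waves(fx$rec, amplitude_percentile = 90))
  expect_lte(n90, n75)
})

test_that("sub-duration deflections are rejected", {
  fs <- 200
  n <- fs * 120
  bg <- 0.05 * gen_powerlaw_signal(n, fs, -2, seed = 3)
  # 0.3 s biphasic deflections: below the duration criterion
  short <- gen_slow_waves(10, 6, c(0.3, 0.3), n, fs, seed = 4)
  ev <- suppressWarnings(detect_slow_waves(recording(bg + short$signal, fs)))
  if (nrow(ev)) {
    hits <- sapply(short$trough_times, function(tt)
      any(abs(ev$trough_time_s - tt) <= 0.05))
    expect_lt(mean(hits), 0.1)
  } else succeed()
})

test_that("event-locked slope course is flat on stationary background", {
  fs <- 200
  n <- fs * 1200
  rec <- recording(gen_powerlaw_signal(n, fs, -2, seed = 5), fs)
  # pseudo-events at arbitrary interior times; a single 0.5 s window fit has
  # SD ~ 4, so per-window means over 300 events carry SEM ~ 0.22
  set.seed(6)
  ev <- data.frame(trough_time_s = sort(runif(300, 5, 1195)))
  locked <- event_locked_slope(rec, ev)
  expect_length(locked$centers, 19)
  expect_within(mean(locked$mean_slope), -2, 0.15)
  expect_lt(max(abs(locked$mean_slope + 2)), 0.75)
  # far-lag windows converge to the unconditional slope
  edge <- abs(locked$centers) >= 2
  expect_lt(abs(mean(locked$mean_slope[edge]) + 2), 0.3)
})

test_that("slope course dips at the trough when high frequencies are suppressed there", {
  fs <- 200
  n <- fs * 400
  sw <- gen_slow_waves(6, 4, c(0.8, 2), n, fs, seed = 8)
  # high-band noise whose envelope vanishes around each trough: the 30-45 Hz
  # fit sees the steep background there and flat noise at the flanks
  set.seed(8)
  hf <- signal::filtfilt(signal::butter(4, 25 / (fs / 2), "high"),
                         rnorm(n))
  env <- rep(1, n)
  for (tt in sw$trough_times) {
    idx <- round((tt + seq(-0.35, 0.35, by = 1 / fs)) * fs)
    idx <- idx[idx >= 1 & idx <= n]
    env[idx] <- 0
  }
  x <- gen_powerlaw_signal(n, fs, -3, seed = 9) + sw$signal + 1.5 * hf * env
  locked <- event_locked_slope(recording(x, fs),
                               data.frame(trough_time_s = sw$trough_times))
  w0 <- which.min(abs(locked$centers))
  expect_identical(which.min(locked$mean_slope), w0)
  expect_lt(locked$mean_slope[w0], min(locked$mean_slope[abs(locked$centers) > 1.5]))
})

test_that("event rates per state follow counts over stage minutes", {
  hyp <- hypnogram(c(rep("N3", 2), rep("REM", 2)))   # one minute each
  ev <- data.frame(trough_time_s = seq(1, 59, by = 2),
                   state = "N3", stringsAsFactors = FALSE)
  rates <- event_rate_by_state(ev, hyp)
  expect_equal(rates$rate_per_min[rates$state == "N3"], 30)
  expect_equal(rates$rate_per_min[rates$state == "REM"], 0)
  expect_true(is.na(rates$rate_per_min[rates$state == "W"]))
})

test_that("detector-derived rates preserve the N3-over-REM incidence ordering", {
  fs <- 200
  hyp <- hypnogram(rep(c("N3", "REM"), each = 4))
  nep <- 30 * fs
  set.seed(10)
  x <- unlist(lapply(seq_along(hyp$labels), function(e) {
    rate <- if (hyp$labels[e] == "N3") 25 else 2
    bg <- gen_powerlaw_signal(nep, fs, -2.5, seed = 200 + e)
    bg + gen_slow_waves(rate, 6, c(0.8, 2), nep, fs, seed = 300 + e)$signal
  }))
  ev <- detect_slow_waves(recording(x, fs), hyp = hyp)
  rates <- event_rate_by_state(ev, hyp, states = c("N3", "REM"))
  expect_gt(rates$rate_per_min[rates$state == "N3"],
            3 * max(rates$rate_per_min[rates$state == "REM"], 1))
})

test_that("trough-window slopes group by state with shrinking SEM", {
  centers <- seq(-2.25, 2.25, by = 0.25)
  w0 <- which.min(abs(centers))
  per_event <- matrix(rnorm(40 * 19, -3, 0.1), 40, 19)
  per_event[1:20, w0] <- rnorm(20, -2.3, 0.1)
  per_event[21:40, w0] <- rnorm(20, -4.0, 0.1)
  locked <- list(centers = centers, per_event = per_event,
                 events_used = data.frame(state = rep(c("W", "N3"), each = 20)))
  g <- trough_slope_by_state(locked, states = c("W", "N3", "REM"))
  expect_within(g$mean_trough_slope[g$state == "W"], -2.3, 0.2)
  expect_within(g$mean_trough_slope[g$state == "N3"], -4.0, 0.2)
  expect_true(is.na(g$mean_trough_slope[g$state == "REM"]))
  # SEM scales as 1/sqrt(n)
  g2 <- trough_slope_by_state(list(centers = centers,
                                   per_event = per_event[c(1:5, 21:40), ],
                                   events_used = data.frame(
                                     state = rep(c("W", "N3"), c(5, 20)))),
                              states = c("W", "N3"))
  expect_gt(g2$sem[g2$state == "W"], g2$sem[g2$state == "N3"])
})
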