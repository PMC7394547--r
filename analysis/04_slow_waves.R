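#!/usr/bin/env Rscript
# Slow-wave analysis: detection against ground truth, per-state incidence,
# and the slow-wave-locked slope time course.
#
# Reads:  results/data/night*  Writes: results/slow_waves/*

suppressMessages(library(slopetrack))

rec <- read_recording("results/data/night")
hyp <- read_hypnogram("results/data/night_hypnogram.txt")
dir.create("results/slow_waves", recursive = TRUE, showWarnings = FALSE)

ev <- detect_slow_waves(rec, channel = 1, hyp = hyp)
write.csv(ev, "results/slow_waves/events.csv", row.names = FALSE)
cat(sprintf("Detected %d slow waves on %s.\n", nrow(ev), rec$channel_labels[1]))

rates <- event_rate_by_state(ev, hyp, states = c("W", "N2", "N3", "REM"))
write.csv(rates, "results/slow_waves/rates_by_state.csv", row.names = FALSE)
cat("\nSlow-wave incidence by state (events/min):\n")
print(rates, digits = 3)

if (nrow(ev) >= 10) {
  locked <- event_locked_slope(rec, ev, channel = 1)
  course <- data.frame(center_s = locked$centers,
                       mean_slope = locked$mean_slope,
                       sem = locked$sem_slope)
  write.csv(course, "results/slow_waves/event_locked_slope.csv",
            row.names = FALSE)
  w0 <- which.min(abs(locked$centers))
  cat(sprintf("\nEvent-locked 30-45 Hz slope: trough window %.2f +/- %.2f, flank mean %.2f\n",
              locked$mean_slope[w0], locked$sem_slope[w0],
              mean(locked$mean_slope[abs(locked$centers) >= 2])))
  by_state <- trough_slope_by_state(locked, states = c("W", "N2", "N3", "REM"))
  write.csv(by_state, "results/slow_waves/trough_slope_by_state.csv",
            row.names = FALSE)
  print(by_state, digits = 3)
}
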