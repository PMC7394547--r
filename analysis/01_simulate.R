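#!/usr/bin/env Rscript
# Simulate the study night used by all downstream analysis scripts: a
# Markov-chain hypnogram with realistic bout structure and a multichannel
# recording whose per-state 1/f exponents follow the published group means
# (wake -1.84, N2 -3.67, N3 -3.46, REM -4.73), with alpha/spindle/theta
# bursts, state-dependent slow-wave rates and an EMG channel.
#
# Writes: results/data/night.{csv,json}, night_hypnogram.txt,
#         night_truth.csv

suppressMessages(library(slopetrack))

seed <- 20240
n_epochs <- 240            # two hours at 30 s epochs: long enough for the
                           # first REM bouts to appear at realistic latency
fs <- 200
n_channels <- 2

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

hyp <- gen_hypnogram(n_epochs, sleep_transition_matrix(), "W", seed = seed)
cat("Simulated hypnogram composition:\n")
print(table(hyp$labels))

sim <- gen_recording(state_profiles(), hyp, n_channels = n_channels,
                     fs = fs, seed = seed)
print(sim$recording)

write_recording(sim$recording, "results/data/night", meta = list(seed = seed))
write_hypnogram(hyp, "results/data/night_hypnogram.txt")
truth <- data.frame(epoch = seq_len(n_epochs), state = sim$truth$states,
                    true_slope = sim$truth$slopes)
write.csv(truth, "results/data/night_truth.csv", row.names = FALSE)

n_troughs <- lengths(sim$truth$trough_times)
cat(sprintf("Injected slow-wave troughs per channel: %s\n",
            paste(n_troughs, collapse = ", ")))
cat("Night written to results/data/\n")
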