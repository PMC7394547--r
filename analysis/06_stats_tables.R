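#!/usr/bin/env Rscript
# Statistical reference tables: the regional electrode contingency tests,
# electrode fractions, multiple-comparison thresholds, permutation tests on
# the per-state slope distributions, and a cluster-permutation demonstration
# on the synthetic 25-channel montage.
#
# Reads:  results/tracking/state_summary.csv  Writes: results/stats/*

suppressMessages(library(slopetrack))

dir.create("results/stats", recursive = TRUE, showWarnings = FALSE)
seed <- 20246

# regional contingency tables (modulated vs not, medial vs lateral)
tabs <- list(
  mPFC_vs_lPFC = matrix(c(24, 15, 4, 58), 2),
  MTL_vs_LTC = matrix(c(33, 13, 15, 66), 2))
cont <- do.call(rbind, lapply(names(tabs), function(nm) {
  r <- chi2_2x2_yates(tabs[[nm]])
  data.frame(comparison = nm, chi2_yates = r$statistic, p = r$p_value,
             chi2_uncorrected = r$statistic_uncorrected)
}))
write.csv(cont, "results/stats/contingency.csv", row.names = FALSE)
cat("Regional contingency (Yates-corrected chi-squared):\n")
print(cont, digits = 4)

fractions <- data.frame(
  quantity = c("anesthesia_seeg_decrease", "sleep_seeg_pattern"),
  count = c(470, 155), total = c(485, 352))
fractions$percent <- 100 * fractions$count / fractions$total
write.csv(fractions, "results/stats/electrode_fractions.csv",
          row.names = FALSE)
cat("\nElectrode fractions:\n"); print(fractions, digits = 4)

thresholds <- data.frame(
  quantity = c("bonferroni_19ch", "p_at_z196", "z_at_p05"),
  value = c(bonferroni_alpha(0.05, 19), z_to_p_two_tailed(1.96),
            qnorm(1 - 0.025)))
write.csv(thresholds, "results/stats/thresholds.csv", row.names = FALSE)

# permutation tests on per-state slope distributions of the simulated night
summ <- read.csv("results/tracking/state_summary.csv")
track <- read.csv("results/tracking/slope_track.csv")
hyp <- read_hypnogram("results/data/night_hypnogram.txt")
ch1 <- subset(track, channel == track$channel[1])
by_state <- split(ch1$slope[seq_along(hyp$labels)], hyp$labels)
if (all(c("W", "N3") %in% names(by_state))) {
  n <- min(lengths(by_state[c("W", "N3")]))
  r <- permutation_t_paired(by_state$W[1:n], by_state$N3[1:n],
                            n_perm = 10000, seed = seed)
  cat(sprintf("\nW vs N3 slope, paired permutation t-test: t = %.2f, p = %.4g, d = %.2f\n",
              r$observed_stat, r$p_value, r$effect_size_d))
  write.csv(data.frame(test = "W_vs_N3_paired_t", t = r$observed_stat,
                       p = r$p_value, d = r$effect_size_d, n_pairs = n),
            "results/stats/permutation_t.csv", row.names = FALSE)
}

# cluster permutation on the synthetic montage: a global state contrast
set.seed(seed)
adj <- adjacency_from_layout(montage25())
subj <- 12
wake <- matrix(rnorm(subj * 25, -1.8, 0.4), subj, 25)
n3 <- matrix(rnorm(subj * 25, -3.4, 0.4), subj, 25)
cl <- cluster_permutation_channels(wake, n3, adj, n_perm = 1000,
                                   seed = seed + 1)
write.csv(cl$clusters, "results/stats/cluster_permutation.csv",
          row.names = FALSE)
cat("\nCluster permutation over the synthetic montage:\n")
print(cl$clusters)
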