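#!/usr/bin/env Rscript
# State discrimination from single features: balanced leave-one-out LDA of
# wake vs REM (and wake vs N3) using the spectral slope versus slow-wave
# power, and the GLM eta-squared decomposition of their unique contributions.
#
# Reads:  results/data/night*  Writes: results/classification/*

suppressMessages(library(slopetrack))

rec <- read_recording("results/data/night")
hyp <- read_hypnogram("results/data/night_hypnogram.txt")
dir.create("results/classification", recursive = TRUE, showWarnings = FALSE)
seed <- 20245

track <- time_resolved_slope(rec, segment_sec = 30, band = c(30, 45))
psd <- compute_psd(rec, "multitaper", segment_sec = 30)
al <- align_to_hypnogram(track, hyp, channel = 1)
so_power <- log10(vapply(al$epoch, function(e)
  mean(psd$per_segment[e, 1, psd$freqs < 1.25]), 0))
feat <- data.frame(stage = al$stage, slope = al$slope, so_power = so_power)

rows <- list(); glm_rows <- list()
for (contrast in list(c("W", "REM"), c("W", "N3"))) {
  sub <- feat[feat$stage %in% contrast, ]
  if (length(unique(sub$stage)) < 2 || min(table(sub$stage)) < 4) next
  for (feature in c("slope", "so_power")) {
    r <- lda_balanced_cv(sub[[feature]], sub$stage, n_repeats = 50,
                         seed = seed + nchar(feature))
    rows[[length(rows) + 1]] <- data.frame(
      comparison = paste(contrast, collapse = "-"), feature_set = feature,
      accuracy_pct = r$accuracy, logit_mean = r$logit_accuracy,
      n_repeats = r$n_repeats, n_per_class = r$n_per_class, seed = seed)
  }
  if (nrow(sub) >= 10) {
    g <- glm_state_model(as.integer(sub$stage == contrast[2]), sub$slope,
                         sub$so_power)
    glm_rows[[length(glm_rows) + 1]] <- data.frame(
      comparison = paste(contrast, collapse = "-"),
      term = names(g$eta_squared), eta_squared = as.numeric(g$eta_squared),
      ss_type = g$ss_type, n = g$n)
  }
}
cls <- do.call(rbind, rows)
write.csv(cls, "results/classification/lda_results.csv", row.names = FALSE)
cat("Balanced LOO-LDA accuracies (percent correct):\n")
print(cls, digits = 4)

if (length(glm_rows)) {
  glm_tab <- do.call(rbind, glm_rows)
  write.csv(glm_tab, "results/classification/glm_eta_squared.csv",
            row.names = FALSE)
  cat("\nGLM unique explained variance (eta squared, Type II SS):\n")
  print(glm_tab, digits = 3)
}
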