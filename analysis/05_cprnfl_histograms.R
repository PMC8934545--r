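#!/usr/bin/env Rscript
# Global circumpapillary thickness by group: the healthy fifth-percentile
# cutoff, how many artifact-bearing healthy eyes sit above it (maps that
# look glaucomatous while the summary metric is normal), and histograms.
# Reads: results/eyes.csv
# Writes: results/g_cprnfl_summary.csv, results/figures/g_histograms.png

library(rnflartifacts)

eyes <- read.csv("results/eyes.csv")
cutoff <- percentile_cutoff(eyes$G_cpRNFL[eyes$group == "HC_norm"], 5)
eyes$below_5th <- eyes$G_cpRNFL < cutoff

summ <- do.call(rbind, lapply(split(eyes, eyes$group), function(d) data.frame(
  group = d$group[1], n = nrow(d),
  mean_G = round(mean(d$G_cpRNFL), 1),
  n_below_5th = sum(d$below_5th),
  n_artifact_above_5th = sum(d$artifact_type != "none" & !d$below_5th &
                               d$group %in% c("HC", "HC_norm")))))
summ <- rbind(summ, data.frame(group = "cutoff_5th_um", n = NA,
                               mean_G = round(cutoff, 1), n_below_5th = NA,
                               n_artifact_above_5th = NA))
write.csv(summ, "results/g_cprnfl_summary.csv", row.names = FALSE)
print(summ)

dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
plot_g_histograms(eyes, cutoff, groups = c("HC_norm", "HC", "EG"),
                  file = "results/figures/g_histograms.png")
message("wrote results/figures/g_histograms.png")
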