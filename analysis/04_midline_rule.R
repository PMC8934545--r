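#!/usr/bin/env Rscript
# Sensitivity/specificity of the vertical midline rule on the simulated
# cohorts, RNFL-only and combined with GCL+, by severity stratum.
# Reads: results/eyes.csv  Writes: results/midline_metrics.csv

library(rnflartifacts)

eyes <- read.csv("results/eyes.csv")
healthy <- c("HC", "HC_norm")
patients <- c("EG", "MG", "AG")

row_of <- function(cm, label) data.frame(
  rule = label, TP = cm$TP, FP = cm$FP, TN = cm$TN, FN = cm$FN,
  sensitivity_pct = round(cm$sensitivity, 1),
  specificity_pct = round(cm$specificity, 1))

ev <- data.frame(group = eyes$group, positive = eyes$midline_positive)
out <- rbind(
  row_of(confusion_metrics(ev, patients, healthy), "midline_all"),
  row_of(confusion_metrics(ev[eyes$group %in% c("EG", healthy), ],
                           "EG", healthy), "midline_EG"),
  row_of(confusion_metrics(ev[eyes$group %in% c("MG", "AG", healthy), ],
                           c("MG", "AG"), healthy), "midline_MG_AG"))
if (!all(is.na(eyes$midline_combined_positive))) {
  evc <- data.frame(group = eyes$group, positive = eyes$midline_combined_positive)
  out <- rbind(out,
    row_of(confusion_metrics(evc, patients, healthy), "midline_combined_GCL"))
}
write.csv(out, "results/midline_metrics.csv", row.names = FALSE)
print(out)
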