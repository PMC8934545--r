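#!/usr/bin/env Rscript
# Fit the age-corrected per-pixel normative models (RNFL and GCL+) from the
# simulated reference cohort and summarize them.
# Reads: scratch/cohorts.rds  Writes: scratch/models.rds, results/normative_summary.csv

library(rnflartifacts)

cohorts <- readRDS("scratch/cohorts.rds")
message("fitting RNFL normative model ...")
model <- fit_normative_model(lapply(cohorts$reference, `[[`, "map"))
message("fitting GCL+ normative model ...")
gcl_model <- fit_normative_model(lapply(cohorts$reference, `[[`, "gcl_map"))

summ <- data.frame(
  layer = c(model$layer, gcl_model$layer),
  n_reference = c(model$n_reference, gcl_model$n_reference),
  age_min = c(model$age_range[1], gcl_model$age_range[1]),
  age_max = c(model$age_range[2], gcl_model$age_range[2]),
  mean_slope_um_per_year = c(mean(model$slope), mean(gcl_model$slope)),
  mean_abs_residual_um = c(mean(abs(model$residuals)),
                           mean(abs(gcl_model$residuals))))
write.csv(summ, "results/normative_summary.csv", row.names = FALSE)
saveRDS(list(model = model, gcl_model = gcl_model), "scratch/models.rds")
print(summ)
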