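#!/usr/bin/env Rscript
# Convert every study eye to probability maps, apply the temporal-disc
# necessary condition, the artifact taxonomy and the vertical midline rule
# (RNFL-only and combined with GCL+), and extract G_cpRNFL.
# Reads: scratch/cohorts.rds, scratch/models.rds
# Writes: results/eyes.csv, results/artifact_tables.csv, figures/*.png

library(rnflartifacts)

cohorts <- readRDS("scratch/cohorts.rds")
models <- readRDS("scratch/models.rds")
cfg <- default_experiment_config()

message("evaluating ", length(cohorts$study), " eyes ...")
eyes <- evaluate_cohort(cohorts$study, models$model, models$gcl_model, cfg)
write.csv(eyes, "results/eyes.csv", row.names = FALSE)

healthy <- eyes[eyes$group %in% c("HC", "HC_norm"), ]
tab <- tabulate_artifacts(healthy$group, healthy$artifact_type)
tables <- rbind(
  data.frame(table = "frequency", key = tab$by_group$group,
             n = tab$by_group$n_artifact, percent = tab$by_group$percent),
  data.frame(table = "taxonomy", key = tab$taxonomy$type,
             n = tab$taxonomy$n, percent = tab$taxonomy$percent))
write.csv(tables, "results/artifact_tables.csv", row.names = FALSE)
print(tables)

# example rendering: the first healthy eye detected with an arcuate artifact
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
hit <- which(eyes$group %in% c("HC", "HC_norm") & eyes$artifact_type == "arcuate")
if (length(hit)) {
  eye <- cohorts$study[[hit[1]]]
  pm <- compute_pmap(eye$map, models$model)
  plot_pmap(pm, file = "results/figures/arcuate_artifact_pmap.png")
  message("wrote results/figures/arcuate_artifact_pmap.png (",
          eyes$eye_id[hit[1]], ")")
}
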