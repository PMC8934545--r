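#' Default experiment configuration
#'
#' Cohort sizes follow the study design the package emulates: 54 healthy
#' controls (HC), 200 healthy eyes from a normative-style group (HC_norm),
#' 32 early (EG), 12 moderate (MG) and 18 advanced (AG) glaucoma eyes,
#' plus a separate 200-eye healthy reference cohort (artifact-free) that
#' the normative model is fitted on. Artifact-mechanism rates default to
#' the frequencies observed in those groups (7\% for HC_norm, 11\% for HC).
#'
#' @return A nested list understood by [run_experiment()].
#' @export
default_experiment_config <- function() {
  list(
    n_reference = 200L,
    groups = c(HC = 54L, HC_norm = 200L, EG = 32L, MG = 12L, AG = 18L),
    artifact_rate = c(HC = 0.11, HC_norm = 0.07),
    noise_sd = 3,
    red_threshold = 1, yellow_threshold = 5,
    rule = rule_config(),
    use_gcl = TRUE,
    gcl_groups = c("HC", "HC_norm", "EG", "MG", "AG")
  )
}

#' Run the end-to-end synthetic experiment
#'
#' Simulates the reference and study cohorts, fits the RNFL (and GCL+)
#' normative models, converts every study eye to probability maps, applies
#' the temporal-disc necessary condition, the artifact taxonomy and the
#' vertical midline rule (RNFL-only and combined RNFL+GCL+), extracts
#' G_cpRNFL on the 3.4-mm circle, and assembles per-group artifact
#' frequencies, the artifact-type table, rule confusion metrics and the
#' G_cpRNFL distributions with the healthy fifth-percentile cutoff.
#' Deterministic for a given seed.
#'
#' @param config A list as from [default_experiment_config()]; missing
#'   entries are filled with the defaults.
#' @param seed Integer seed.
#' @param out_dir Optional directory; when given, the report is written as
#'   \code{report.json} and the per-eye table as \code{eyes.csv}.
#' @return The report list (invisibly contains the per-eye data frame as
#'   \code{$eyes}).
#' @export
run_experiment <- function(config = default_experiment_config(), seed = 1,
                           out_dir = NULL) {
  defaults <- default_experiment_config()
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  check_config(config)
  base <- as.integer(seed %% 1000000000L)
  ref_layers <- if (isTRUE(config$use_gcl)) c("RNFL", "GCLplus") else "RNFL"

  ref <- generate_cohort(list(groups = c(HC_ref = config$n_reference),
                              artifact_rate = 0, noise_sd = config$noise_sd,
                              layers = ref_layers),
                         seed = base + 101L)
  model <- fit_normative_model(lapply(ref, `[[`, "map"))
  gcl_model <- if (isTRUE(config$use_gcl))
    fit_normative_model(lapply(ref, `[[`, "gcl_map")) else NULL
  rm(ref)

  cohort <- list()
  snext <- base + 202L
  for (gname in names(config$groups)) {
    rate <- if (gname %in% names(config$artifact_rate))
      config$artifact_rate[[gname]] else 0
    layers <- if (isTRUE(config$use_gcl) && gname %in% config$gcl_groups)
      c("RNFL", "GCLplus") else "RNFL"
    part <- generate_cohort(list(groups = config$groups[gname],
                                 artifact_rate = rate,
                                 noise_sd = config$noise_sd, layers = layers),
                            seed = snext)
    cohort <- c(cohort, part)
    snext <- snext + 1L
  }

  eyes <- evaluate_cohort(cohort, model, gcl_model, config)
  build_report(eyes, config, seed, out_dir)
}

check_config <- function(config) {
  if (is.null(names(config$groups)) || any(config$groups < 1))
    stop("config error at groups: named positive sizes required")
  if (!inherits(config$rule, "rule_config"))
    stop("config error at rule: must be a rule_config()")
  invisible(config)
}

#' Evaluate every eye of a simulated cohort
#'
#' @param cohort Output of [generate_cohort()].
#' @param model RNFL [fit_normative_model()] result.
#' @param gcl_model Optional GCL+ model (enables the combined midline rule).
#' @param config Experiment configuration (thresholds and rule).
#' @return A data frame, one row per eye: group and ground-truth labels,
#'   necessary condition, artifact type, midline outcomes and G_cpRNFL.
#' @export
evaluate_cohort <- function(cohort, model, gcl_model = NULL,
                            config = default_experiment_config()) {
  rule <- config$rule
  rows <- lapply(cohort, function(eye) {
    pmap <- compute_pmap(eye$map, model, config$red_threshold,
                         config$yellow_threshold)
    regs <- extract_abnormal_regions(pmap, rule)
    necessary <- any(vapply(regs, temporal_disc_condition, logical(1)))
    atype <- classify_artifact_type(regs)
    midline <- vertical_midline_rule(pmap, rule)
    midline_comb <- NA_character_
    if (!is.null(gcl_model) && !is.null(eye$gcl_map)) {
      gpm <- compute_pmap(eye$gcl_map, gcl_model, config$red_threshold,
                          config$yellow_threshold)
      midline_comb <- vertical_midline_rule(pmap, rule, gcl_pmap = gpm)
    }
    prof <- extract_circle_profile(eye$map)
    l <- eye$labels
    data.frame(eye_id = l$eye_id, group = l$group, laterality = l$laterality,
               age = l$age, true_artifact = l$artifact,
               true_mechanism = l$mechanism,
               defect_kind = l$defect$kind, defect_depth = l$defect$depth_fraction,
               MD_242 = l$MD_242,
               necessary_condition = necessary, artifact_type = atype,
               midline_positive = midline == "positive",
               midline_combined_positive = if (is.na(midline_comb)) NA
                 else midline_comb == "positive",
               G_cpRNFL = global_cprnfl(prof),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

build_report <- function(eyes, config, seed, out_dir) {
  healthy <- c("HC", "HC_norm")
  patients <- c("EG", "MG", "AG")
  hc <- eyes[eyes$group %in% healthy, ]
  tab <- tabulate_artifacts(hc$group, hc$artifact_type)

  cm <- confusion_metrics(
    data.frame(group = eyes$group, positive = eyes$midline_positive),
    patients, healthy)
  cm_eg <- confusion_metrics(
    data.frame(group = eyes$group, positive = eyes$midline_positive)[
      eyes$group %in% c("EG", healthy), ], "EG", healthy)
  cm_mgag <- confusion_metrics(
    data.frame(group = eyes$group, positive = eyes$midline_positive)[
      eyes$group %in% c("MG", "AG", healthy), ], c("MG", "AG"), healthy)
  has_comb <- !is.na(eyes$midline_combined_positive)
  cm_comb <- if (any(has_comb))
    confusion_metrics(
      data.frame(group = eyes$group,
                 positive = eyes$midline_combined_positive)[has_comb, ],
      patients, healthy) else NULL

  # fifth-percentile cutoff from the normative-style healthy group when
  # present, else from whatever healthy eyes the run has
  gpool <- eyes$G_cpRNFL[eyes$group == "HC_norm"]
  if (length(gpool) < 20) gpool <- eyes$G_cpRNFL[eyes$group %in% healthy]
  cutoff <- percentile_cutoff(gpool, 5, min_n = min(5, length(gpool)))
  eyes$below_5th <- eyes$G_cpRNFL < cutoff
  ord <- eyes[order(eyes$G_cpRNFL), c("eye_id", "group", "G_cpRNFL",
                                      "artifact_type", "midline_positive")]

  report <- list(
    seed = seed,
    config_echo = list(groups = as.list(config$groups),
                       artifact_rate = as.list(config$artifact_rate),
                       noise_sd = config$noise_sd,
                       red_threshold = config$red_threshold,
                       yellow_threshold = config$yellow_threshold,
                       rule = unclass(config$rule)),
    artifact_frequency = tab$by_group,
    artifact_taxonomy = tab$taxonomy,
    midline_rule = unclass(cm),
    midline_rule_EG = unclass(cm_eg),
    midline_rule_MGAG = unclass(cm_mgag),
    midline_rule_combined_gcl = if (!is.null(cm_comb)) unclass(cm_comb),
    g_cprnfl = list(cutoff_5th_hcnorm = cutoff,
                    group_means = tapply(eyes$G_cpRNFL, eyes$group, mean),
                    n_healthy_artifact_above_cutoff = sum(
                      eyes$group %in% healthy & eyes$artifact_type != "none" &
                        !eyes$below_5th)),
    eyes_by_thickness = ord,
    eyes = eyes
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(eyes, file.path(out_dir, "eyes.csv"), row.names = FALSE)
    jsonlite::write_json(report[setdiff(names(report), "eyes")],
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         force = TRUE)
  }
  report
}
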