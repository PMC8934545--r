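#' Generate a labeled synthetic cohort
#'
#' Draws eyes group by group. Healthy groups (\code{HC}, \code{HC_norm},
#' \code{HC_ref}) sample anatomy from the healthy distribution; with
#' probability \code{artifact_rate} an eye receives an artifact mechanism --
#' a major arcuate bundle (with its vessel) displaced toward the temporal
#' raphe, a thinned papillomacular/temporal baseline, or both -- recorded
#' as its ground-truth mechanism label. Patient groups (\code{EG},
#' \code{MG}, \code{AG}) receive parametric wedge defects whose depth and
#' width grow with severity, plus a matching visual-field summary series.
#'
#' @param spec A list with \code{groups} (named integer vector of group
#'   sizes), optional \code{artifact_rate} (probability of an artifact
#'   mechanism in healthy eyes, default 0.07), optional \code{noise_sd}
#'   (um, default 3), optional \code{os_rate} (probability an eye is OS,
#'   default 0.5), optional \code{layers} (subset of "RNFL", "GCLplus";
#'   default "RNFL"; an empty vector draws labels and anatomy only, without
#'   synthesizing maps).
#' @param seed Integer seed; identical spec + seed reproduces the cohort
#'   bit-for-bit.
#' @return A list of eyes; each eye is a list with \code{map} (RNFL
#'   [thickness_map()]), optionally \code{gcl_map}, \code{labels} (group,
#'   mechanism, artifact flag, defect, MD) and \code{vf} (a data frame of
#'   visual-field records, patients only).
#' @export
generate_cohort <- function(spec, seed = 1) {
  if (is.null(spec$groups) || length(spec$groups) == 0 || any(spec$groups < 1))
    stop("configuration error: spec$groups must name at least one group with n >= 1")
  groups <- spec$groups
  bad <- setdiff(names(groups), c("HC", "HC_norm", "HC_ref", "EG", "MG", "AG"))
  if (length(bad)) stop("configuration error: unknown group(s) ", paste(bad, collapse = ", "))
  artifact_rate <- spec$artifact_rate %||% 0.07
  noise_sd <- spec$noise_sd %||% 3
  os_rate <- spec$os_rate %||% 0.5
  layers <- spec$layers %||% "RNFL"

  withr::with_seed(as.integer(seed), {
    eyes <- list()
    idx <- 0L
    for (gname in names(groups)) {
      for (k in seq_len(groups[[gname]])) {
        idx <- idx + 1L
        eyes[[idx]] <- draw_eye(gname, idx, artifact_rate, noise_sd,
                                os_rate, layers)
      }
    }
    eyes
  })
}

draw_eye <- function(group, idx, artifact_rate, noise_sd, os_rate, layers) {
  healthy <- group %in% c("HC", "HC_norm", "HC_ref")
  g <- scan_geometry()

  # the acquisition protocol centers and registers the scan on the fovea,
  # so landmark positions vary little in the scan frame; disc-fovea
  # distance and vertical disc offset carry the anatomical variation
  fovea <- c(stats::rnorm(1, 8.4, 0.08), stats::rnorm(1, 4.5, 0.08))
  D <- stats::rnorm(1, 4.5, 0.15)
  disc <- c(fovea[1] - D, fovea[2] + stats::rnorm(1, 0, 0.12))
  peaks <- c(min(max(stats::rnorm(1, 65, 5), 30), 150),
             -min(max(stats::rnorm(1, 65, 5), 30), 150))
  voffs <- c(stats::rnorm(1, 12, 3), stats::rnorm(1, -12, 3))
  pmb <- exp(stats::rnorm(1, 0, 0.08))
  age <- stats::runif(1, 40, 80)
  disc_r <- min(max(stats::rnorm(1, 0.9, 0.07), 0.7), 1.15)

  mechanism <- "none"
  if (healthy && stats::runif(1) < artifact_rate) {
    mechanism <- sample(c("displaced_bundle", "thin_temporal", "both"),
                        1, prob = c(0.65, 0.25, 0.10))
    if (mechanism %in% c("displaced_bundle", "both")) {
      # the affected arcuate bundle (with its vessel) sits displaced toward
      # the temporal raphe, in the far tail of the population distribution
      # of entry angles; the norm then expects bundle tissue superior /
      # inferior to where this eye carries it, which reads as an arcuate
      # red band at the typical bundle position
      which_b <- sample(1:2, 1)
      displaced <- 65 - stats::rnorm(1, 30, 5)
      peaks[which_b] <- min(max(displaced, 30), 160) *
        if (which_b == 1) 1 else -1
    }
    if (mechanism %in% c("thin_temporal", "both"))
      pmb <- pmb * stats::runif(1, 0.35, 0.5)
  }

  anat <- eye_anatomy(fovea_center = fovea, disc_center = disc,
                      disc_radius = disc_r, laterality = "OD", age = age,
                      bundle_peak_angles = peaks, vessel_offsets = voffs,
                      pmb_scale = pmb)

  defect <- defect_spec("none")
  md <- stats::rnorm(1, 0, 0.8)
  if (!healthy) {
    side <- sample(c(1, -1), 1)
    center <- side * min(max(stats::rnorm(1, 65, 10), 35), 120)
    defect <- switch(group,
      # a fraction of early defects are spatially limited and terminate
      # before the fovea midline (~5.5 mm from the disc)
      EG = defect_spec("arcuate", center, stats::runif(1, 15, 40),
                       stats::runif(1, 0.3, 0.6), "EG",
                       max_radius_mm = stats::runif(1, 4, 10)),
      MG = defect_spec(if (stats::runif(1) < 0.2) "combined" else "arcuate",
                       center, stats::runif(1, 40, 70),
                       stats::runif(1, 0.6, 0.8), "MG"),
      AG = defect_spec("combined", center, stats::runif(1, 70, 110),
                       stats::runif(1, 0.8, 0.95), "AG"))
    md <- switch(group,
      EG = stats::runif(1, -5.5, -1),
      MG = stats::runif(1, -11.5, -6.5),
      AG = stats::runif(1, -18, -12.1))
  }

  map_seed <- sample.int(.Machine$integer.max - 1L, 1)
  map <- if ("RNFL" %in% layers)
    synthesize_thickness_map(anat, defect, noise_sd, map_seed) else NULL
  gcl <- if ("GCLplus" %in% layers)
    synthesize_thickness_map(anat, defect, noise_sd, map_seed + 1L,
                             layer = "GCLplus") else NULL

  is_os <- stats::runif(1) < os_rate
  if (is_os) {
    if (!is.null(map)) map <- mirror_to_os(map)
    if (!is.null(gcl)) gcl <- mirror_to_os(gcl)
  }

  vf <- if (healthy) NULL else patient_vf_series(md, defect)
  list(map = map,
       gcl_map = gcl,
       labels = list(eye_id = sprintf("%s_%03d", group, idx), group = group,
                     artifact = mechanism != "none", mechanism = mechanism,
                     defect = defect, MD_242 = md, age = age,
                     laterality = if (is_os) "OS" else "OD"),
       vf = vf)
}

# Reflect an OD-frame retina-view map into a native left-eye (OS) frame.
mirror_to_os <- function(map) {
  map$values <- map$values[, ncol(map$values):1, drop = FALSE]
  map$anatomy <- transform_anatomy(map$anatomy, mirror_h = TRUE)
  map$od_frame <- FALSE
  map
}

# Three reliable, abnormal, hemifield-consistent visits on both patterns;
# the lost hemifield is opposite the retinal side of the structural defect.
patient_vf_series <- function(md, defect) {
  hemi <- if (defect$wedge_center_angle > 0) "inferior" else "superior"
  data.frame(
    test_pattern = rep(c("24-2", "10-2"), each = 3),
    date = rep(1:3, 2),
    MD = md + stats::rnorm(6, 0, 0.3),
    MD_pcat = "p<0.05",
    PSD_pcat = "p<0.01",
    GHT = "outside_normal",
    FP_rate = stats::runif(6, 0, 10),
    FN_rate = stats::runif(6, 0, 10),
    fixation_loss_rate = stats::runif(6, 0, 20),
    abnormal_hemifield = hemi,
    stringsAsFactors = FALSE
  )
}

#' Cohort manifest
#'
#' One row per eye: id, group, laterality, age, ground-truth artifact
#' mechanism and defect parameters.
#'
#' @param cohort Output of [generate_cohort()].
#' @return A data frame.
#' @export
cohort_manifest <- function(cohort) {
  do.call(rbind, lapply(cohort, function(e) {
    l <- e$labels
    data.frame(eye_id = l$eye_id, group = l$group, laterality = l$laterality,
               age = l$age, artifact = l$artifact, mechanism = l$mechanism,
               defect_kind = l$defect$kind,
               defect_center = l$defect$wedge_center_angle,
               defect_width = l$defect$wedge_width,
               defect_depth = l$defect$depth_fraction,
               MD_242 = l$MD_242, stringsAsFactors = FALSE)
  }))
}
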