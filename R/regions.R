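#' Configuration of the spatial decision rules
#'
#' @param level Which probability-map level counts as abnormal when forming
#'   regions: \code{"red_only"} (percentile below the red threshold) or
#'   \code{"red_or_yellow"}.
#' @param min_area_mm2 Regions smaller than this are discarded (mm^2).
#' @param disc_halo_mm Width of the annulus outside the disc boundary that
#'   defines "near" the disc (mm).
#' @param midline_min_extent_mm Required abnormal extent past the vertical
#'   fovea midline, on the nasal-field side (mm).
#' @param quadrant_halfangle Half-angle of the temporal quadrant /
#'   maculo-papillary sector (degrees, default 45).
#' @return An object of class \code{rule_config}.
#' @export
rule_config <- function(level = c("red_only", "red_or_yellow"),
                        min_area_mm2 = 0.1, disc_halo_mm = 1.0,
                        midline_min_extent_mm = 0.25,
                        quadrant_halfangle = 45) {
  level <- match.arg(level)
  stopifnot(min_area_mm2 >= 0, disc_halo_mm >= 0, midline_min_extent_mm >= 0,
            quadrant_halfangle > 0, quadrant_halfangle <= 90)
  structure(list(level = level, min_area_mm2 = min_area_mm2,
                 disc_halo_mm = disc_halo_mm,
                 midline_min_extent_mm = midline_min_extent_mm,
                 quadrant_halfangle = quadrant_halfangle),
            class = "rule_config")
}

# 8-connected component labeling. EBImage::bwlabel is 4-connected, so labels
# that touch diagonally are merged through a label graph.
label_components8 <- function(mask) {
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]     # down-right diagonal
  a2 <- lab[-nr, -1]; b2 <- lab[-1, -nc]     # down-left diagonal
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  nlab <- max(lab)
  if (nrow(pairs) > 0) {
    gr <- igraph::graph_from_edgelist(unique(pairs), directed = FALSE)
    gr <- igraph::add_vertices(gr, max(0, nlab - igraph::vcount(gr)))
    comp <- igraph::components(gr)$membership
    lab[lab > 0] <- comp[lab[lab > 0]]
  }
  # compact labels to 1..k
  u <- sort(unique(lab[lab > 0]))
  lab[lab > 0] <- match(lab[lab > 0], u)
  lab
}

#' Extract abnormal regions from a probability map
#'
#' Forms 8-connected components of pixels at the configured level, drops
#' components below the area floor, computes each region's geometry flags
#' (temporal-disc contact, midline crossing, zone membership) and returns
#' them sorted by descending area.
#'
#' @param pmap A \code{probability_map} in field view, OD frame.
#' @param config A [rule_config()].
#' @return A list of \code{abnormal_region} objects, each with
#'   \code{pixels} (two-column matrix of row/col indices), \code{area_mm2},
#'   \code{touches_temporal_disc}, \code{crosses_midline},
#'   \code{nasal_extent_mm} and \code{zone_fractions}.
#' @export
extract_abnormal_regions <- function(pmap, config = rule_config()) {
  stopifnot(inherits(pmap, "probability_map"))
  if (pmap$view != "field" || !pmap$od_frame)
    stop("pmap must be in field view, OD frame")
  mask <- if (config$level == "red_only") pmap$category == 2L
          else pmap$category >= 1L
  lab <- label_components8(mask)
  if (max(lab) == 0) return(list())
  g <- scan_geometry()
  px_area <- g$dy * g$dx
  regs <- list()
  for (k in seq_len(max(lab))) {
    pix <- which(lab == k, arr.ind = TRUE)
    area <- nrow(pix) * px_area
    if (area < config$min_area_mm2) next
    regs[[length(regs) + 1L]] <-
      region_geometry(pix, area, pmap$anatomy, config)
  }
  regs[order(-vapply(regs, function(r) r$area_mm2, 0))]
}

# Geometry flags for one pixel set (field view, OD frame).
region_geometry <- function(pix, area, anatomy, config) {
  g <- scan_geometry()
  x <- (pix[, 2] - 0.5) * g$dx
  y <- (pix[, 1] - 0.5) * g$dy
  pol <- disc_polar(anatomy, x, y)

  halo <- pol$r >= anatomy$disc_radius &
    pol$r <= anatomy$disc_radius + config$disc_halo_mm
  temporal_half <- pol$u >= 0     # half-plane containing the fovea
  touches <- any(halo & temporal_half)

  fovea_x <- anatomy$fovea_center[1]
  nasal_extent <- max(x) - fovea_x  # nasal visual field = temporal retina
  crosses <- any(x > fovea_x) && any(x <= fovea_x) &&
    nasal_extent >= config$midline_min_extent_mm

  qa <- config$quadrant_halfangle
  aa <- abs(pol$ang)
  ztemp <- mean(aa <= qa)
  zsup <- mean(pol$ang > qa & pol$ang < 180 - qa)
  zinf <- mean(pol$ang < -qa & pol$ang > -(180 - qa))
  # maculo-papillary sector: temporal wedge truncated at the fovea
  mp <- any(aa <= qa & pol$u >= 0 & pol$r <= axis_frame(anatomy)$length)

  structure(list(pixels = pix, area_mm2 = area,
                 touches_temporal_disc = touches,
                 crosses_midline = crosses,
                 nasal_extent_mm = nasal_extent,
                 intersects_maculopapillary = mp,
                 zone_fractions = c(temporal_quadrant = ztemp,
                                    superior_arcuate = zsup,
                                    inferior_arcuate = zinf)),
            class = "abnormal_region")
}

#' Temporal-disc necessary condition
#'
#' TRUE iff the region intersects the annulus of width \code{disc_halo_mm}
#' outside the disc boundary, restricted to the temporal half-plane (the
#' half bounded by the line through the disc center perpendicular to the
#' disc-fovea axis that contains the fovea). A red region meeting this
#' condition is the necessary condition for calling a map abnormal.
#'
#' @param region An \code{abnormal_region}.
#' @param anatomy,config Used only when the region was built elsewhere;
#'   regions from [extract_abnormal_regions()] carry the flag already.
#' @return Logical.
#' @export
temporal_disc_condition <- function(region, anatomy = NULL, config = NULL) {
  if (!is.null(anatomy)) {
    if (is.null(anatomy$disc_center)) stop("metadata error: missing landmarks")
    region <- region_geometry(region$pixels, region$area_mm2, anatomy,
                              config %||% rule_config())
  }
  isTRUE(region$touches_temporal_disc)
}

#' Vertical midline crossing of one region
#'
#' TRUE iff the (8-connected) region has abnormal pixels strictly on the
#' nasal-field side of the vertical line through the fovea, pixels on the
#' temporal side (so the crossing is contiguous within the region), and a
#' nasal extent of at least \code{midline_min_extent_mm}.
#'
#' @inheritParams temporal_disc_condition
#' @return Logical.
#' @export
crosses_vertical_midline <- function(region, anatomy = NULL, config = NULL) {
  if (!is.null(anatomy)) {
    region <- region_geometry(region$pixels, region$area_mm2, anatomy,
                              config %||% rule_config())
  }
  isTRUE(region$crosses_midline)
}

#' Classify the artifact pattern of a map's qualifying regions
#'
#' Only regions passing the temporal-disc condition are considered.
#' \code{arcuate}: some qualifying region has at least half its area in the
#' superior or the inferior arcuate sector. \code{temporal_Q}: some
#' qualifying region has at least half its area in the temporal quadrant
#' and intersects the maculo-papillary sector. \code{both}: both criteria
#' met (by one or more regions). Sectors are disc-centered and measured
#' from the disc-fovea axis: temporal +/- 45 deg, superior (45, 135),
#' inferior (-135, -45).
#'
#' @param regions List of \code{abnormal_region}s.
#' @param anatomy,config See [temporal_disc_condition()].
#' @return One of "none", "arcuate", "temporal_Q", "both".
#' @export
classify_artifact_type <- function(regions, anatomy = NULL, config = NULL) {
  qual <- Filter(function(r) temporal_disc_condition(r, anatomy, config),
                 regions)
  if (length(qual) == 0) return("none")
  arc <- any(vapply(qual, function(r)
    max(r$zone_fractions[c("superior_arcuate", "inferior_arcuate")]) >= 0.5,
    logical(1)))
  tq <- any(vapply(qual, function(r)
    r$zone_fractions[["temporal_quadrant"]] >= 0.5 &&
      isTRUE(r$intersects_maculopapillary), logical(1)))
  if (arc && tq) "both" else if (arc) "arcuate" else if (tq) "temporal_Q"
  else "none"
}

#' The vertical midline rule
#'
#' Positive iff some qualifying region (one passing the temporal-disc
#' necessary condition) crosses the vertical fovea midline. With a GCL+
#' probability map supplied, the crossing test is applied to 8-connected
#' components of the union of both abnormal masks (the combined variant:
#' an RNFL arcuate that stops at the midline can be carried across by a
#' contiguous GCL+ abnormality).
#'
#' @param pmap RNFL \code{probability_map}, field view, OD frame.
#' @param config A [rule_config()].
#' @param gcl_pmap Optional GCL+ \code{probability_map}, same frame.
#' @return "positive" or "negative".
#' @export
vertical_midline_rule <- function(pmap, config = rule_config(),
                                  gcl_pmap = NULL) {
  if (is.null(gcl_pmap)) {
    regs <- extract_abnormal_regions(pmap, config)
  } else {
    if (!all(dim(gcl_pmap$category) == dim(pmap$category)))
      stop("shape error: misaligned probability maps")
    level_mask <- function(pm) if (config$level == "red_only")
      pm$category == 2L else pm$category >= 1L
    union_mask <- level_mask(pmap) | level_mask(gcl_pmap)
    pm2 <- pmap
    pm2$category <- matrix(2L * union_mask, nrow(union_mask))
    regs <- extract_abnormal_regions(pm2, config)
  }
  qual <- Filter(function(r) isTRUE(r$touches_temporal_disc), regs)
  if (any(vapply(qual, function(r) isTRUE(r$crosses_midline), logical(1))))
    "positive" else "negative"
}
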