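#' Wide-field thickness map
#'
#' A 2-D scalar grid of layer thickness (micrometres) on the fixed
#' 256 x 512 wide-field grid (9 x 12 mm), together with its physical scale,
#' the eye's landmarks and a view tag. In \emph{retina view} row 1 is the
#' superior retina; \emph{field view} is the vertical flip, so the top of
#' the map corresponds to the superior visual field (inferior retina).
#' Left eyes (OS) are additionally mirrored horizontally into the right-eye
#' (OD) frame when converted to field view, so all downstream geometry runs
#' in a single frame.
#'
#' @param values 256 x 512 numeric matrix of thickness in um (finite, >= 0).
#' @param anatomy An [eye_anatomy()] in the same frame as \code{values}.
#' @param view "retina" or "field".
#' @param layer "RNFL" or "GCLplus".
#' @param od_frame Logical; \code{TRUE} once an OS map has been mirrored
#'   into the OD frame (always \code{TRUE} for OD eyes).
#' @return An object of class \code{thickness_map}.
#' @export
thickness_map <- function(values, anatomy, view = c("retina", "field"),
                          layer = c("RNFL", "GCLplus"),
                          od_frame = anatomy$laterality == "OD") {
  view <- match.arg(view)
  layer <- match.arg(layer)
  g <- scan_geometry()
  if (!is.matrix(values) || nrow(values) != g$rows || ncol(values) != g$cols)
    stop("shape error: values must be a ", g$rows, " x ", g$cols, " matrix")
  if (any(!is.finite(values)) || any(values < 0))
    stop("thickness values must be finite and >= 0")
  structure(list(values = values, anatomy = anatomy, view = view,
                 layer = layer, od_frame = od_frame,
                 pixel_size = c(dy = g$dy, dx = g$dx)),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("thickness_map [%s, %s view%s]: %d x %d px, %g x %g mm, mean %.1f um\n",
              x$layer, x$view, if (x$od_frame) ", OD frame" else "",
              nrow(x$values), ncol(x$values), 9, 12, mean(x$values)))
  invisible(x)
}

#' Convert a map between retina view and field view
#'
#' Field view is the vertical flip of retina view (top of the map = superior
#' visual field = inferior retina). On the retina-to-field conversion an OS
#' map is also mirrored horizontally into the OD frame; the field-to-retina
#' conversion undoes both, so the operation is involutive. Landmarks and
#' bundle angles are transformed along with the grid.
#'
#' @param x A \code{thickness_map} or \code{probability_map}.
#' @return The same class of object in the other view.
#' @export
field_view <- function(x) {
  if (is.null(x$view)) stop("metadata error: object carries no view tag")
  if (is.null(x$anatomy$laterality)) stop("metadata error: missing laterality")
  to_field <- x$view == "retina"
  was_os <- if (to_field) x$anatomy$laterality == "OS" else attr(x, "was_os") %||% FALSE
  do_mirror <- was_os
  flipv <- TRUE
  grids <- intersect(names(x), c("values", "percentile", "category"))
  for (nm in grids) {
    m <- x[[nm]]
    m <- m[nrow(m):1, , drop = FALSE]
    if (do_mirror) m <- m[, ncol(m):1, drop = FALSE]
    x[[nm]] <- m
  }
  x$anatomy <- transform_anatomy(x$anatomy, flip_v = flipv, mirror_h = do_mirror)
  if (to_field) {
    x$view <- "field"
    x$od_frame <- TRUE
    attr(x, "was_os") <- was_os
  } else {
    x$view <- "retina"
    x$od_frame <- x$anatomy$laterality == "OD"
    attr(x, "was_os") <- NULL
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a map as single-page 32-bit float TIFF plus JSON sidecar
#'
#' The grid goes to \code{<stem>.tif}; scale, landmarks, view, layer and any
#' extra labels go to \code{<stem>.json}.
#'
#' @param map A \code{thickness_map}.
#' @param stem Path without extension.
#' @param labels Optional named list of extra metadata stored verbatim.
#' @return \code{stem}, invisibly.
#' @export
write_map <- function(map, stem, labels = NULL) {
  # tiff stores [0,1] floats faithfully when asked for 32-bit samples;
  # keep um units by writing the raw values with reduced-precision off
  tiff::writeTIFF(map$values / 1000, paste0(stem, ".tif"),
                  bits.per.sample = 32L)
  a <- map$anatomy
  meta <- list(pixel_size_mm = as.list(map$pixel_size), view = map$view,
               layer = map$layer, od_frame = map$od_frame,
               scale_divisor = 1000,
               anatomy = list(fovea_center = a$fovea_center,
                              disc_center = a$disc_center,
                              disc_radius = a$disc_radius,
                              laterality = a$laterality, age = a$age,
                              bundle_peak_angles = a$bundle_peak_angles,
                              vessel_offsets = a$vessel_offsets,
                              pmb_scale = a$pmb_scale),
               labels = labels)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname write_map
#' @export
read_map <- function(stem) {
  vals <- tiff::readTIFF(paste0(stem, ".tif"))
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  an <- meta$anatomy
  a <- eye_anatomy(fovea_center = an$fovea_center, disc_center = an$disc_center,
                   disc_radius = an$disc_radius, laterality = an$laterality,
                   age = an$age, bundle_peak_angles = an$bundle_peak_angles,
                   vessel_offsets = an$vessel_offsets, pmb_scale = an$pmb_scale)
  m <- thickness_map(vals * meta$scale_divisor, a, view = meta$view,
                     layer = meta$layer, od_frame = meta$od_frame)
  attr(m, "labels") <- meta$labels
  m
}
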