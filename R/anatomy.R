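#' Scan geometry of the wide-field volume
#'
#' The wide-field swept-source scan covers 9 mm (vertical, 256 B-scans) by
#' 12 mm (horizontal, 512 A-scans). All maps in this package live on that
#' fixed grid. Pixel \code{[i, j]} (1-based, row-major, origin upper-left)
#' has its center at \code{x = (j - 0.5) * dx}, \code{y = (i - 0.5) * dy}
#' millimetres; \code{y} increases downward (half-open pixel convention).
#'
#' @return A list with \code{rows}, \code{cols}, \code{height_mm},
#'   \code{width_mm}, and the pixel pitch \code{dy}, \code{dx} (mm).
#' @export
scan_geometry <- function() {
  list(rows = 256L, cols = 512L, height_mm = 9, width_mm = 12,
       dy = 9 / 256, dx = 12 / 512)
}

#' Eye anatomy for the thickness-map simulator
#'
#' Landmarks and anatomical-variation parameters of one eye, in the scan
#' frame (mm, retina view). Angles are measured from the disc-to-fovea axis
#' (temporal direction = 0 degrees), positive toward the superior retina.
#'
#' @param fovea_center Numeric length 2, (x, y) of the fovea in mm.
#' @param disc_center Numeric length 2, (x, y) of the optic disc center in mm.
#' @param disc_radius Disc radius in mm (> 0).
#' @param laterality "OD" (right) or "OS" (left eye).
#' @param age Age in years, within [18, 90].
#' @param bundle_peak_angles Length-2 numeric, entry angles (degrees) of the
#'   superior and inferior major arcuate bundles at the disc; superior in
#'   (0, 180), inferior in (-180, 0).
#' @param vessel_offsets Length-2 numeric, angular displacement (degrees) of
#'   the major vessel ridges relative to the two bundle peaks.
#' @param pmb_scale Multiplier on the papillomacular/temporal baseline
#'   amplitude (1 = typical; low values thin the temporal raphe region).
#' @return An object of class \code{eye_anatomy}.
#' @export
eye_anatomy <- function(fovea_center = c(8.4, 4.5),
                        disc_center = c(3.9, 4.5),
                        disc_radius = 0.9,
                        laterality = c("OD", "OS"),
                        age = 50,
                        bundle_peak_angles = c(65, -65),
                        vessel_offsets = c(12, -12),
                        pmb_scale = 1) {
  laterality <- match.arg(laterality)
  a <- structure(list(
    fovea_center = as.numeric(fovea_center),
    disc_center = as.numeric(disc_center),
    disc_radius = as.numeric(disc_radius),
    laterality = laterality,
    age = as.numeric(age),
    bundle_peak_angles = as.numeric(bundle_peak_angles),
    vessel_offsets = as.numeric(vessel_offsets),
    pmb_scale = as.numeric(pmb_scale)
  ), class = "eye_anatomy")
  validate_anatomy(a)
  a
}

validate_anatomy <- function(a) {
  g <- scan_geometry()
  inside <- function(p) p[1] >= 0 && p[1] <= g$width_mm &&
    p[2] >= 0 && p[2] <= g$height_mm
  if (!inside(a$fovea_center) || !inside(a$disc_center))
    stop("landmark-geometry error: fovea and disc centers must lie inside the scan frame")
  if (a$disc_radius <= 0)
    stop("landmark-geometry error: disc_radius must be > 0")
  if (a$age < 18 || a$age > 90)
    stop("landmark-geometry error: age must be within [18, 90]")
  bp <- a$bundle_peak_angles
  if (length(bp) != 2 || !(bp[1] > 0 && bp[1] < 180) || !(bp[2] > -180 && bp[2] < 0))
    stop("landmark-geometry error: superior peak must be in (0, 180), inferior in (-180, 0)")
  # in the native frame the disc sits nasal to the fovea: left of it for OD,
  # right of it for a native (un-mirrored) OS scan
  dxf <- a$fovea_center[1] - a$disc_center[1]
  ok <- if (a$laterality == "OD") dxf > 0 else dxf < 0
  if (!ok)
    stop("landmark-geometry error: disc must be nasal to the fovea for the stated laterality")
  invisible(a)
}

#' @export
print.eye_anatomy <- function(x, ...) {
  cat(sprintf(
    "eye_anatomy: %s, age %.0f | fovea (%.2f, %.2f) mm, disc (%.2f, %.2f) r=%.2f mm\n",
    x$laterality, x$age, x$fovea_center[1], x$fovea_center[2],
    x$disc_center[1], x$disc_center[2], x$disc_radius))
  cat(sprintf("  bundle peaks %+.1f / %+.1f deg, vessel offsets %+.1f / %+.1f deg, pmb %.2f\n",
              x$bundle_peak_angles[1], x$bundle_peak_angles[2],
              x$vessel_offsets[1], x$vessel_offsets[2], x$pmb_scale))
  invisible(x)
}

# Unit vectors of the disc-fovea axis frame in image coordinates (y down).
# u points from disc toward fovea (temporal), v toward the superior retina.
# The +90 deg rotation u -> v holds in the OD frame; a native (un-mirrored)
# OS frame has opposite handedness, so the rotation sign follows laterality.
axis_frame <- function(anatomy) {
  d <- anatomy$fovea_center - anatomy$disc_center
  # math coordinates: y up
  um <- c(d[1], -d[2]) / sqrt(sum(d^2))
  s <- if (identical(anatomy$laterality, "OS")) -1 else 1
  vm <- s * c(-um[2], um[1])
  list(u = um, v = vm, length = sqrt(sum(d^2)))
}

# Polar coordinates of points about the disc, relative to the disc-fovea
# axis: radius (mm) and angle (degrees, positive superior). x, y are image
# coordinates (y down), vectorized.
disc_polar <- function(anatomy, x, y) {
  ax <- axis_frame(anatomy)
  px <- x - anatomy$disc_center[1]
  py <- -(y - anatomy$disc_center[2])  # to math coords
  ur <- px * ax$u[1] + py * ax$u[2]
  vr <- px * ax$v[1] + py * ax$v[2]
  list(r = sqrt(px^2 + py^2), ang = atan2(vr, ur) * 180 / pi,
       u = ur, v = vr)
}

# Signed angular difference a - b wrapped to (-180, 180]
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  d[d > 180] <- d[d > 180] - 360
  d
}

# Matrices of pixel-center coordinates (mm), image convention.
pixel_grid <- function() {
  g <- scan_geometry()
  x <- (seq_len(g$cols) - 0.5) * g$dx
  y <- (seq_len(g$rows) - 0.5) * g$dy
  list(x = matrix(x, g$rows, g$cols, byrow = TRUE),
       y = matrix(y, g$rows, g$cols),
       geom = g)
}

# Landmark transform under vertical flip and/or horizontal mirror of the grid.
transform_anatomy <- function(a, flip_v = FALSE, mirror_h = FALSE) {
  g <- scan_geometry()
  f <- a$fovea_center; d <- a$disc_center
  bp <- a$bundle_peak_angles; vo <- a$vessel_offsets
  if (flip_v) {
    f[2] <- g$height_mm - f[2]; d[2] <- g$height_mm - d[2]
    bp <- -rev(bp); vo <- -rev(vo)
  }
  if (mirror_h) {
    f[1] <- g$width_mm - f[1]; d[1] <- g$width_mm - d[1]
    a$laterality <- if (a$laterality == "OD") "OS" else "OD"
    # angle sense about the disc-fovea axis is preserved by mirroring because
    # the axis itself is mirrored with the landmarks
  }
  a$fovea_center <- f; a$disc_center <- d
  a$bundle_peak_angles <- bp; a$vessel_offsets <- vo
  a
}
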