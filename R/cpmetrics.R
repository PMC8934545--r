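#' Extract the circumpapillary profile on the 3.4-mm circle
#'
#' Bilinear interpolation of the thickness grid at \code{n_samples} equally
#' spaced angles on the circle of the given diameter around the disc
#' center, in TSNIT order: starting temporal (toward the fovea) and
#' proceeding through superior, nasal and inferior. Maps are brought to the
#' standard retina-view OD frame first, so OD and mirrored-OS profiles
#' agree.
#'
#' @param map A [thickness_map()].
#' @param diameter_mm Circle diameter (mm), default 3.4.
#' @param n_samples Number of angular samples, default 256.
#' @return An object of class \code{circle_profile} with
#'   \code{thickness_by_angle} (um), \code{angles_deg}, \code{diameter_mm}
#'   and \code{center}.
#' @export
extract_circle_profile <- function(map, diameter_mm = 3.4, n_samples = 256L) {
  std <- standard_frame(map)
  g <- scan_geometry()
  a <- std$anatomy
  radius <- diameter_mm / 2
  margin_x <- min(a$disc_center[1], g$width_mm - a$disc_center[1])
  margin_y <- min(a$disc_center[2], g$height_mm - a$disc_center[2])
  if (radius > margin_x || radius > margin_y)
    stop(sprintf(
      "geometry error: %.2f-mm circle exceeds the scan frame (margins %.2f x %.2f mm)",
      diameter_mm, margin_x, margin_y))
  ax <- axis_frame(a)
  ang <- (seq_len(n_samples) - 1) / n_samples * 2 * pi  # 0 = temporal, + = superior
  dirx <- cos(ang) * ax$u[1] + sin(ang) * ax$v[1]
  diry <- -(cos(ang) * ax$u[2] + sin(ang) * ax$v[2])    # back to image y-down
  px <- a$disc_center[1] + radius * dirx
  py <- a$disc_center[2] + radius * diry
  # pracma::interp2 wants ascending grid coordinates of the value matrix
  xg <- (seq_len(g$cols) - 0.5) * g$dx
  yg <- (seq_len(g$rows) - 0.5) * g$dy
  vals <- pracma::interp2(xg, yg, std$values, px, py, method = "linear")
  structure(list(thickness_by_angle = vals,
                 angles_deg = ang * 180 / pi,
                 diameter_mm = diameter_mm, center = a$disc_center),
            class = "circle_profile")
}

#' Global circumpapillary thickness
#'
#' Arithmetic mean of the circle-profile samples (G_cpRNFL when the profile
#' comes from an RNFL map).
#'
#' @param profile A \code{circle_profile}.
#' @return Mean thickness in um.
#' @export
global_cprnfl <- function(profile) {
  stopifnot(inherits(profile, "circle_profile"))
  mean(profile$thickness_by_angle)
}

#' Empirical percentile cutoff of a reference distribution
#'
#' Midrank-interpolated empirical percentile (the convention with plotting
#' positions k/(n+1); \code{stats::quantile} type 6). Used for the
#' bottom-fifth-percentile threshold of the healthy G_cpRNFL distribution.
#'
#' @param values Numeric vector (at least \code{min_n} values).
#' @param q Percent in (0, 100), default 5.
#' @param min_n Minimum reference size, default 20.
#' @return The cutoff in the units of \code{values}.
#' @export
percentile_cutoff <- function(values, q = 5, min_n = 20) {
  if (length(values) < min_n)
    stop("insufficient-reference error: need at least ", min_n, " values")
  unname(stats::quantile(values, q / 100, type = 6))
}
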