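#' Glaucomatous defect specification for the simulator
#'
#' Defects attenuate tissue along nerve-fiber-bundle trajectories inside an
#' angular wedge at the disc. \code{arcuate} removes a wedge of bundles;
#' \code{diffuse_temporal} attenuates a broad temporal wedge (papillomacular
#' region and temporal quadrant); \code{combined} applies both (pointwise
#' maximum of the two attenuations).
#'
#' @param kind "none", "arcuate", "diffuse_temporal" or "combined".
#' @param wedge_center_angle Wedge center at the disc, degrees from the
#'   disc-fovea axis (positive superior).
#' @param wedge_width Full angular width of the wedge, degrees (> 0 unless
#'   kind = "none").
#' @param depth_fraction Fraction of baseline thickness removed, in [0, 1].
#' @param severity_label "HC", "EG", "MG" or "AG".
#' @param max_radius_mm Radial extent of the damage from the disc center
#'   (mm); \code{Inf} (the default) runs the wedge to the scan edge.
#'   Spatially limited early defects terminate before the fovea midline.
#' @return An object of class \code{defect_spec}.
#' @export
defect_spec <- function(kind = c("none", "arcuate", "diffuse_temporal", "combined"),
                        wedge_center_angle = 65, wedge_width = 30,
                        depth_fraction = 0, severity_label = "HC",
                        max_radius_mm = Inf) {
  kind <- match.arg(kind)
  if (depth_fraction < 0 || depth_fraction > 1)
    stop("depth_fraction must be in [0, 1]")
  if (kind != "none" && wedge_width <= 0)
    stop("wedge_width must be > 0 for a non-trivial defect")
  if (max_radius_mm <= 0) stop("max_radius_mm must be > 0")
  structure(list(kind = kind, wedge_center_angle = wedge_center_angle,
                 wedge_width = wedge_width, depth_fraction = depth_fraction,
                 severity_label = match.arg(severity_label,
                                            c("HC", "EG", "MG", "AG")),
                 max_radius_mm = max_radius_mm),
            class = "defect_spec")
}

# Angular decay of a bundle's polar angle with distance from the disc:
# a trajectory entering at theta0 sits at angle theta0 * traj_decay(r) when
# it reaches radius r. The quadratic-exponential form bends every bundle
# toward the temporal raphe (angle 0) without ever crossing it, and leaves
# the papillomacular axis (theta0 = 0) straight.
TRAJ_C <- 0.03  # 1/mm^2

traj_decay <- function(r, disc_radius) {
  exp(-TRAJ_C * pmax(r - disc_radius, 0)^2)
}

#' Nerve-fiber bundle trajectory
#'
#' Parametric course of the bundle entering the optic disc at
#' \code{entry_angle} (degrees from the disc-fovea axis, positive superior).
#' The papillomacular bundle (0 deg) runs straight from the disc boundary to
#' the fovea; all other bundles arc around the macula, their polar angle
#' decaying toward -- but never crossing -- the horizontal raphe (the ray
#' from the fovea directed away from the disc). The curve is truncated at
#' the scan-frame edge.
#'
#' @param anatomy An [eye_anatomy()].
#' @param entry_angle Entry angle at the disc, degrees in (-180, 180).
#' @param step Radial step in mm.
#' @return A matrix with columns \code{x}, \code{y} (mm, image coordinates).
#' @export
bundle_trajectory <- function(anatomy, entry_angle, step = 0.05) {
  validate_anatomy(anatomy)
  if (entry_angle <= -180 || entry_angle >= 180)
    stop("entry_angle must be in (-180, 180)")
  g <- scan_geometry()
  ax <- axis_frame(anatomy)
  rd <- anatomy$disc_radius
  r_end <- if (abs(entry_angle) < 1e-12) ax$length else
    sqrt(g$width_mm^2 + g$height_mm^2)
  r <- seq(rd, r_end, by = step)
  ang <- entry_angle * traj_decay(r, rd) * pi / 180
  # position = disc + r * (cos(ang) u + sin(ang) v), in math coords
  px <- anatomy$disc_center[1] +
    r * (cos(ang) * ax$u[1] + sin(ang) * ax$v[1])
  py <- anatomy$disc_center[2] -
    r * (cos(ang) * ax$u[2] + sin(ang) * ax$v[2])
  inside <- px >= 0 & px <= g$width_mm & py >= 0 & py <= g$height_mm
  if (any(!inside)) {
    first_out <- which(!inside)[1]
    keep <- seq_len(max(first_out - 1, 1))
  } else keep <- seq_along(r)
  cbind(x = px[keep], y = py[keep])
}

# Closed-form baseline thickness template. Every pixel is assigned the entry
# angle theta0 of the (unique) trajectory through it by inverting the
# angular-decay map, then receives bundle, nasal, papillomacular-plateau and
# vessel contributions. All amplitudes in um.
baseline_template <- function(anatomy, params = template_params()) {
  p <- params
  grd <- pixel_grid()
  pol <- disc_polar(anatomy, grd$x, grd$y)
  rd <- anatomy$disc_radius
  dec <- traj_decay(pol$r, rd)
  theta0 <- pmax(pmin(pol$ang / dec, 180), -180)

  wg <- function(delta, s) exp(-ang_diff(delta, 0)^2 / (2 * s^2))
  bp <- anatomy$bundle_peak_angles
  # entry-angle variation is a near-disc phenomenon: individual bundles
  # (displaced or not) rejoin the canalized common arcuate course within a
  # few mm of the disc, so their effective center tapers from the eye's own
  # entry angle to the population home course with radius
  rejoin <- exp(-(pmax(pol$r - rd, 0) / p$bundle_rejoin)^2)
  home <- c(p$bundle_home, -p$bundle_home)
  c1 <- home[1] + (bp[1] - home[1]) * rejoin
  c2 <- home[2] + (bp[2] - home[2]) * rejoin
  # bundles also fan out: their angular footprint widens with radius
  bsd <- p$bundle_sd * (1 + pmax(pol$r - rd, 0) / p$bundle_widen)
  bundles <- p$bundle_amp * (wg(theta0 - c1, bsd) +
                             wg(theta0 - c2, bsd))
  nasal <- p$nasal_amp * wg(abs(theta0) - 180, p$nasal_sd)

  # papillomacular plateau: ridge along the disc-fovea axis, fading nasally
  # past the disc and temporally past the fovea
  ax <- axis_frame(anatomy)
  D <- ax$length
  along <- pol$u                 # axis-projection from disc center
  perp <- pol$v
  axial <- ifelse(along < 0, exp(along / 0.8),
                  ifelse(along > D, exp(-(along - D) / p$pmb_tail), 1))
  # papillomacular amplitude variation expresses near the disc and blends
  # into the canalized perifoveal profile: the pmb_scale effect tapers to 1
  # within ~1 mm of the fovea
  wts <- pmin(pmax((D - 0.8 - along) / 1.2, 0), 1)
  eff_scale <- 1 + (anatomy$pmb_scale - 1) * wts
  plateau <- p$pmb_amp * eff_scale *
    exp(-perp^2 / (2 * p$pmb_sd^2)) * axial *
    exp(-pmax(pol$r - rd, 0) / p$pmb_decay)

  # vessel ridges follow the (rejoining) bundles at the stated angular
  # offsets; lateral distance measured at matched radius
  vess <- 0
  centers <- list(c1, c2)
  for (k in 1:2) {
    tv <- centers[[k]] + anatomy$vessel_offsets[k]
    lat <- abs(ang_diff(pol$ang, tv * dec)) * pi / 180 * pol$r
    vess <- vess + p$vessel_amp * exp(-lat^2 / (2 * p$vessel_sd^2))
  }

  radial <- exp(-pmax(pol$r - rd, 0) / p$radial_decay)
  tissue <- (bundles + nasal) * radial + plateau + vess
  # foveal pit and optic-disc interior carry (almost) no measurable RNFL
  fx <- anatomy$fovea_center; dfov <- sqrt((grd$x - fx[1])^2 + (grd$y - fx[2])^2)
  pit <- 1 - exp(-dfov^2 / (2 * p$fovea_sd^2))
  tissue <- tissue * pit
  tissue[pol$r < rd] <- 0
  agefac <- 1 - p$age_rate * (anatomy$age - p$age_ref)
  p$floor + tissue * agefac
}

#' Baseline-template parameters
#'
#' Amplitudes and length scales of the synthetic wide-field RNFL baseline:
#' two arcuate bundle ridges, a nasal ridge, the papillomacular plateau,
#' vessel ridges, radial thinning away from the disc, a foveal pit, a global
#' measurement floor and a linear age-thinning factor. Defaults produce a
#' double-hump TSNIT circumpapillary profile with a global mean near
#' 95-100 um at age 50.
#'
#' @param bundle_amp,bundle_sd Arcuate ridge amplitude (um) and angular
#'   width (deg) at the disc.
#' @param bundle_widen Radial scale (mm) of bundle fan-out: the angular
#'   width grows by a factor (1 + (r - disc_radius)/bundle_widen).
#' @param bundle_home Magnitude (deg) of the population's common arcuate
#'   entry course that individual bundles rejoin peripherally.
#' @param bundle_rejoin Radial scale (mm) of that rejoining taper.
#' @param nasal_amp,nasal_sd Nasal ridge amplitude (um) and width (deg).
#' @param pmb_amp,pmb_sd,pmb_decay,pmb_tail Papillomacular plateau amplitude
#'   (um), perpendicular width (mm), radial decay (mm) and temporal tail
#'   past the fovea (mm).
#' @param vessel_amp,vessel_sd Vessel ridge amplitude (um) and width (mm).
#' @param radial_decay Radial e-folding length of bundle thinning (mm).
#' @param fovea_sd Foveal-pit radius parameter (mm).
#' @param floor Measurement floor added everywhere (um).
#' @param age_rate Fractional thinning per year; \code{age_ref} its anchor.
#' @param age_ref Reference age (years).
#' @return A named list.
#' @export
template_params <- function(bundle_amp = 140, bundle_sd = 22,
                            bundle_widen = 6, bundle_home = 65,
                            bundle_rejoin = 2.5,
                            nasal_amp = 85, nasal_sd = 50,
                            pmb_amp = 60, pmb_sd = 1.2, pmb_decay = 5,
                            pmb_tail = 0.25,
                            vessel_amp = 30, vessel_sd = 0.15,
                            radial_decay = 3, fovea_sd = 0.45,
                            floor = 12, age_rate = 0.002, age_ref = 50) {
  as.list(environment())
}

# Defect attenuation field in [0, 1]: fraction of baseline removed at each
# pixel. Wedges are hard-edged in entry-angle space so the removed fraction
# along affected trajectories is exactly depth_fraction.
defect_attenuation <- function(anatomy, defect) {
  grd <- pixel_grid()
  if (defect$kind == "none" || defect$depth_fraction == 0)
    return(matrix(0, nrow(grd$x), ncol(grd$x)))
  pol <- disc_polar(anatomy, grd$x, grd$y)
  rd <- anatomy$disc_radius
  theta0 <- pmax(pmin(pol$ang / traj_decay(pol$r, rd), 180), -180)
  att <- matrix(0, nrow(grd$x), ncol(grd$x))
  rmax <- defect$max_radius_mm %||% Inf
  wedge <- function(center, width, depth) {
    depth * (abs(ang_diff(theta0, center)) <= width / 2 & pol$r >= rd &
               pol$r <= rmax)
  }
  if (defect$kind %in% c("arcuate", "combined"))
    att <- pmax(att, wedge(defect$wedge_center_angle, defect$wedge_width,
                           defect$depth_fraction))
  if (defect$kind %in% c("diffuse_temporal", "combined"))
    att <- pmax(att, wedge(0, max(defect$wedge_width, 90),
                           defect$depth_fraction *
                             if (defect$kind == "combined") 0.6 else 1))
  att
}

#' Synthesize a wide-field thickness map
#'
#' Baseline anatomy template, multiplied by (1 - defect attenuation) inside
#' the defect wedge, plus i.i.d. Gaussian measurement noise clipped at zero.
#' Deterministic for a given seed; with \code{kind = "none"} and
#' \code{noise_sd = 0} the baseline template is returned bit-for-bit.
#'
#' @param anatomy An [eye_anatomy()].
#' @param defect A [defect_spec()].
#' @param noise_sd Noise standard deviation in um (>= 0).
#' @param seed Integer seed for the noise draw.
#' @param layer "RNFL" or "GCLplus".
#' @param params Template parameters, see [template_params()].
#' @return A retina-view [thickness_map()].
#' @export
synthesize_thickness_map <- function(anatomy, defect = defect_spec("none"),
                                     noise_sd = 3, seed = 1,
                                     layer = c("RNFL", "GCLplus"),
                                     params = template_params()) {
  layer <- match.arg(layer)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  validate_anatomy(anatomy)
  base <- if (layer == "RNFL") baseline_template(anatomy, params)
          else gcl_template(anatomy)
  att <- if (layer == "RNFL") defect_attenuation(anatomy, defect)
         else gcl_defect_attenuation(anatomy, defect)
  vals <- base * (1 - att)
  if (noise_sd > 0) {
    noise <- withr::with_seed(as.integer(seed), {
      matrix(stats::rnorm(length(vals), 0, noise_sd), nrow(vals), ncol(vals))
    })
    vals <- pmax(vals + noise, 0)
  }
  m <- thickness_map(vals, anatomy, view = "retina", layer = layer)
  attr(m, "defect") <- defect
  m
}

# Macular ganglion-cell (GCL+) template: an annular mound around the fovea
# with a central pit, fading beyond ~3.5 mm eccentricity.
gcl_template <- function(anatomy, amp = 85, ring_r = 1.6, ring_sd = 0.9,
                         floor = 15, age_rate = 0.002, age_ref = 50) {
  grd <- pixel_grid()
  fx <- anatomy$fovea_center
  d <- sqrt((grd$x - fx[1])^2 + (grd$y - fx[2])^2)
  pit <- 1 - exp(-d^2 / (2 * 0.35^2))
  mound <- amp * exp(-(d - ring_r)^2 / (2 * ring_sd^2)) * (d <= ring_r) +
    amp * exp(-(d - ring_r)^2 / (2 * (2.2 * ring_sd)^2)) * (d > ring_r)
  agefac <- 1 - age_rate * (anatomy$age - age_ref)
  floor + mound * pit * agefac
}

# Ganglion-cell counterpart of a glaucomatous defect: the macular hemifield
# on the defect side thins, with a soft edge at the horizontal midline.
gcl_defect_attenuation <- function(anatomy, defect) {
  grd <- pixel_grid()
  if (defect$kind == "none" || defect$depth_fraction == 0)
    return(matrix(0, nrow(grd$x), ncol(grd$x)))
  fx <- anatomy$fovea_center
  d <- sqrt((grd$x - fx[1])^2 + (grd$y - fx[2])^2)
  ax <- axis_frame(anatomy)
  # superior-retina side has positive v about the fovea
  px <- grd$x - fx[1]; py <- -(grd$y - fx[2])
  v <- px * ax$v[1] + py * ax$v[2]
  side <- sign(defect$wedge_center_angle)
  if (defect$kind == "diffuse_temporal") side <- 0
  edge <- if (side == 0) 1 else 1 / (1 + exp(-side * v / 0.15))
  0.8 * defect$depth_fraction * edge * (d <= 3.5)
}
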