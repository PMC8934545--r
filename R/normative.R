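#' Fit an age-corrected per-pixel normative model
#'
#' Per-pixel ordinary least squares of thickness on age across the
#' reference cohort, with the per-pixel reference residuals retained as an
#' empirical quantile table for percentile lookup. Maps are first brought
#' into the standard frame (retina view, OD frame; OS maps mirrored). If the
#' reference ages span less than \code{min_age_span} years the slope is
#' fixed at 0 with a warning (the intercept then is the reference mean).
#'
#' @param reference_maps List of [thickness_map()]s of one layer, each with
#'   its age in \code{anatomy$age}.
#' @param min_reference Minimum cohort size (default 20).
#' @param min_age_span Minimum age range (years) for slope estimation.
#' @return An object of class \code{normative_model}: per-pixel
#'   \code{slope} (um/year) and \code{intercept} (um, at age 0) matrices,
#'   the \code{residuals} matrix (pixels x n, each row sorted), and
#'   metadata \code{n_reference}, \code{age_range}, \code{layer}.
#' @export
fit_normative_model <- function(reference_maps, min_reference = 20,
                                min_age_span = 10) {
  n <- length(reference_maps)
  if (n < min_reference)
    stop("insufficient-reference error: need at least ", min_reference,
         " reference maps, got ", n)
  g <- scan_geometry()
  layer <- reference_maps[[1]]$layer
  ages <- numeric(n)
  tmat <- matrix(0, g$rows * g$cols, n)
  for (i in seq_len(n)) {
    m <- reference_maps[[i]]
    if (m$layer != layer) stop("shape error: mixed layers in reference set")
    if (!all(dim(m$values) == c(g$rows, g$cols)))
      stop("shape error: heterogeneous grids in reference set")
    m <- standard_frame(m)
    tmat[, i] <- as.vector(m$values)
    ages[i] <- m$anatomy$age
  }
  span <- diff(range(ages))
  if (span < min_age_span) {
    warning("reference ages span < ", min_age_span,
            " years; age slope fixed at 0")
    slope <- numeric(nrow(tmat))
    intercept <- rowMeans(tmat)
  } else {
    ac <- ages - mean(ages)
    slope <- (tmat %*% ac) / sum(ac^2)
    intercept <- rowMeans(tmat) - slope * mean(ages)
  }
  pred <- intercept %*% t(rep(1, n)) + slope %*% t(ages)
  resid <- tmat - pred
  # sort each pixel's residual table (row-wise) without an R-level loop
  idx <- order(row(resid), resid)
  resid <- matrix(resid[idx], nrow(resid), ncol(resid), byrow = TRUE)
  structure(list(slope = matrix(slope, g$rows, g$cols),
                 intercept = matrix(intercept, g$rows, g$cols),
                 residuals = resid,
                 n_reference = n, age_range = range(ages), layer = layer),
            class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("normative_model [%s]: n = %d, ages %.0f-%.0f, mean slope %.3f um/yr\n",
              x$layer, x$n_reference, x$age_range[1], x$age_range[2],
              mean(x$slope)))
  invisible(x)
}

# Bring a map to the standard analysis frame: retina view, OD frame.
standard_frame <- function(map) {
  if (map$view == "field") map <- field_view(map)  # back to retina first
  if (map$anatomy$laterality == "OS") {
    map$values <- map$values[, ncol(map$values):1, drop = FALSE]
    map$anatomy <- transform_anatomy(map$anatomy, mirror_h = TRUE)
    map$od_frame <- TRUE
  }
  map
}

#' Convert a thickness map to a probability (percentile) map
#'
#' Each pixel's age-corrected residual (observed minus the model's
#' age-prediction) is ranked within the reference residual table by
#' midrank: percentile = (1 + #\{table < obs\} + #\{table = obs\}/2) x
#' 100 / (n_reference + 1), so the attainable range is
#' (100/(n+1), 100 n/(n+1)). Categories: \code{abnormal} ("red") below
#' \code{red_threshold}, \code{borderline} ("yellow") below
#' \code{yellow_threshold}. The result is returned in field view, OD frame.
#'
#' @param map A [thickness_map()] on the model's grid and layer.
#' @param model A [fit_normative_model()] result.
#' @param red_threshold,yellow_threshold Percentile cutoffs
#'   (0 < red < yellow < 50); defaults 1 and 5.
#' @return An object of class \code{probability_map} with \code{percentile}
#'   and \code{category} grids ("normal"/"borderline"/"abnormal" coded
#'   0/1/2), in field view.
#' @export
compute_pmap <- function(map, model, red_threshold = 1, yellow_threshold = 5) {
  if (!(red_threshold > 0 && red_threshold < yellow_threshold &&
        yellow_threshold < 50))
    stop("thresholds must satisfy 0 < red < yellow < 50")
  if (map$layer != model$layer)
    stop("shape error: map layer ", map$layer, " does not match model layer ",
         model$layer)
  g <- scan_geometry()
  if (!all(dim(map$values) == c(g$rows, g$cols)))
    stop("shape error: map grid does not match model grid")
  std <- standard_frame(map)
  obs <- as.vector(std$values) -
    (as.vector(model$intercept) + as.vector(model$slope) * std$anatomy$age)
  n <- model$n_reference
  less <- rowSums(model$residuals < obs)
  ties <- rowSums(model$residuals == obs)
  pct <- (1 + less + ties / 2) * 100 / (n + 1)
  pctm <- matrix(pct, g$rows, g$cols)
  cat_m <- matrix(0L, g$rows, g$cols)
  cat_m[pctm < yellow_threshold] <- 1L
  cat_m[pctm < red_threshold] <- 2L
  pm <- structure(list(percentile = pctm, category = cat_m,
                       anatomy = std$anatomy, view = "retina",
                       od_frame = TRUE, layer = map$layer,
                       thresholds = c(red = red_threshold,
                                      yellow = yellow_threshold)),
                  class = "probability_map")
  field_view(pm)
}

#' @export
print.probability_map <- function(x, ...) {
  n <- length(x$category)
  cat(sprintf(
    "probability_map [%s, %s view]: %.2f%% abnormal (red), %.2f%% borderline (yellow)\n",
    x$layer, x$view, 100 * mean(x$category == 2L), 100 * mean(x$category == 1L)))
  invisible(x)
}
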