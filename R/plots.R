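#' Render a probability map in the familiar green/yellow/red scheme
#'
#' @param pmap A \code{probability_map} (field view).
#' @param file Optional PNG path; when given the plot is written there.
#' @param overlay Draw the disc circle and the vertical fovea midline.
#' @export
plot_pmap <- function(pmap, file = NULL, overlay = TRUE) {
  if (!is.null(file)) grDevices::png(file, width = 900, height = 480)
  on.exit(if (!is.null(file)) grDevices::dev.off(), add = TRUE)
  g <- scan_geometry()
  cols <- c("#1faa34", "#f2d21f", "#d62114")  # normal / borderline / abnormal
  ys <- (seq_len(g$rows) - 0.5) * g$dy
  # reversed y-limits draw row 1 (map top) at the top of the plot
  graphics::image(x = (seq_len(g$cols) - 0.5) * g$dx, y = ys,
                  z = t(pmap$category),
                  ylim = rev(range(ys)),
                  zlim = c(0, 2), col = cols, useRaster = TRUE,
                  xlab = "x (mm)", ylab = "y (mm)", asp = 1,
                  main = sprintf("%s p-map (%s view)", pmap$layer, pmap$view))
  if (overlay) {
    a <- pmap$anatomy
    th <- seq(0, 2 * pi, length.out = 181)
    graphics::lines(a$disc_center[1] + a$disc_radius * cos(th),
                    a$disc_center[2] + a$disc_radius * sin(th), lwd = 2)
    graphics::abline(v = a$fovea_center[1], lwd = 2)
  }
  invisible(pmap)
}

#' Histogram of G_cpRNFL by group with the healthy fifth-percentile cutoff
#'
#' @param eyes Per-eye data frame from [evaluate_cohort()] (needs
#'   \code{G_cpRNFL} and \code{group}).
#' @param cutoff The fifth-percentile threshold (um).
#' @param groups Groups to show, one panel each.
#' @param file Optional PNG path.
#' @export
plot_g_histograms <- function(eyes, cutoff,
                              groups = c("HC_norm", "HC", "EG"),
                              file = NULL) {
  if (!is.null(file)) grDevices::png(file, width = 600, height = 260 * length(groups))
  on.exit(if (!is.null(file)) grDevices::dev.off(), add = TRUE)
  op <- graphics::par(mfrow = c(length(groups), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  rng <- range(eyes$G_cpRNFL)
  brks <- seq(floor(rng[1]) - 2, ceiling(rng[2]) + 2, by = 2)
  for (gr in groups) {
    v <- eyes$G_cpRNFL[eyes$group == gr]
    graphics::hist(v, breaks = brks, col = "grey80", border = "white",
                   main = gr, xlab = "G_cpRNFL (um)")
    graphics::abline(v = cutoff, col = "red", lwd = 2)
    graphics::abline(v = mean(v), lty = 2)
  }
  invisible(NULL)
}
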