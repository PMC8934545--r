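test_that("region extraction matches a brute-force flood fill on random small grids", {
  lab8 <- rnflartifacts:::label_components8
  withr::with_seed(11, {
    for (i in 1:60) {
      nr <- sample(3:32, 1); nc <- sample(3:32, 1)
      mask <- matrix(runif(nr * nc) < runif(1, 0.2, 0.6), nr, nc)
      got <- lab8(mask)
      want <- flood_fill_label(mask)
      # same partition: relabeling-invariant comparison
      expect_equal(max(got), max(want))
      if (max(want) > 0) {
        key <- paste(got[mask], want[mask])
        expect_equal(length(unique(key)), max(want))
      }
    }
  })
})

test_that("abnormal regions are 8-connected components above the area floor, sorted by area", {
  cfg <- rule_config(min_area_mm2 = 0)
  g <- scan_geometry()

  # all-normal map: no regions
  pm <- pmap_from_mask(matrix(0L, g$rows, g$cols))
  expect_equal(length(extract_abnormal_regions(pm, cfg)), 0)

  # two disjoint blocks separated by normal pixels: exactly two equal areas
  m <- matrix(0L, g$rows, g$cols)
  m[30:40, 30:40] <- 2L
  m[120:130, 300:310] <- 2L
  regs <- extract_abnormal_regions(pmap_from_mask(m), cfg)
  expect_equal(length(regs), 2)
  expect_equal(regs[[1]]$area_mm2, regs[[2]]$area_mm2)
  expect_equal(regs[[1]]$area_mm2, 121 * g$dy * g$dx)

  # a diagonal chain is one region under 8-connectivity
  md <- matrix(0L, g$rows, g$cols)
  md[cbind(40:60, 40:60)] <- 2L
  expect_equal(length(extract_abnormal_regions(pmap_from_mask(md), cfg)), 1)

  # area floor removes specks; area accounting is pixel-exact
  speck <- matrix(0L, g$rows, g$cols); speck[10, 10] <- 2L
  expect_equal(length(extract_abnormal_regions(
    pmap_from_mask(speck), rule_config(min_area_mm2 = 0.1))), 0)
  one <- extract_abnormal_regions(pmap_from_mask(speck), cfg)[[1]]
  expect_equal(one$area_mm2, g$dy * g$dx)

  # red_or_yellow level includes borderline pixels
  yellow <- block_mask(2, 3, 2, 3, value = 1L)
  expect_equal(length(extract_abnormal_regions(pmap_from_mask(yellow), cfg)), 0)
  expect_equal(length(extract_abnormal_regions(
    pmap_from_mask(yellow), rule_config("red_or_yellow", min_area_mm2 = 0))), 1)
})

test_that("the temporal-disc condition detects annulus contact in the temporal half", {
  a <- eye_anatomy()   # disc at (3.9, 4.5), fovea at (8.4, 4.5)
  cfg <- rule_config(min_area_mm2 = 0)
  # region entirely nasal of the disc: false
  nasal <- block_mask(0.5, 1.5, 4, 5)
  r <- extract_abnormal_regions(pmap_from_mask(nasal, a), cfg)[[1]]
  expect_false(temporal_disc_condition(r))
  # single pixel on the temporal disc boundary: true (boundary inclusive)
  g <- scan_geometry()
  m <- matrix(0L, g$rows, g$cols)
  bx <- a$disc_center[1] + a$disc_radius + 0.02
  m[round(4.5 / g$dy), round(bx / g$dx)] <- 2L
  r <- extract_abnormal_regions(pmap_from_mask(m, a), cfg)[[1]]
  expect_true(temporal_disc_condition(r))
  # same radius but nasal side: false
  m2 <- matrix(0L, g$rows, g$cols)
  nx <- a$disc_center[1] - a$disc_radius - 0.02
  m2[round(4.5 / g$dy), round(nx / g$dx)] <- 2L
  r2 <- extract_abnormal_regions(pmap_from_mask(m2, a), cfg)[[1]]
  expect_false(temporal_disc_condition(r2))
  # beyond the halo: false
  m3 <- block_mask(a$disc_center[1] + a$disc_radius + 1.2,
                   a$disc_center[1] + a$disc_radius + 1.6, 4.3, 4.7)
  r3 <- extract_abnormal_regions(pmap_from_mask(m3, a), cfg)[[1]]
  expect_false(temporal_disc_condition(r3))
})

test_that("midline crossing needs contiguous abnormality with nasal extent", {
  a <- eye_anatomy()
  cfg <- rule_config(min_area_mm2 = 0, midline_min_extent_mm = 0.5)
  # entirely temporal-field side (x < fovea): false
  r <- extract_abnormal_regions(
    pmap_from_mask(block_mask(5, 7, 3, 3.5, base = NULL), a), cfg)[[1]]
  expect_false(crosses_vertical_midline(r))
  # band from the disc across the fovea line, 2 mm past it: true
  band <- block_mask(4.5, a$fovea_center[1] + 2, 3, 3.4)
  r2 <- extract_abnormal_regions(pmap_from_mask(band, a), cfg)[[1]]
  expect_true(crosses_vertical_midline(r2))
  expect_gt(r2$nasal_extent_mm, 1.9)
  # grazing past the line by less than the required extent: false
  graze <- block_mask(4.5, a$fovea_center[1] + 0.2, 3, 3.4)
  r3 <- extract_abnormal_regions(pmap_from_mask(graze, a), cfg)[[1]]
  expect_false(crosses_vertical_midline(r3))
})

test_that("artifact taxonomy separates arcuate from temporal-quadrant patterns", {
  a <- eye_anatomy()
  cfg <- rule_config(min_area_mm2 = 0)
  expect_equal(classify_artifact_type(list()), "none")

  # arcuate band in the superior-field sector touching the temporal disc
  g <- scan_geometry()
  grd <- rnflartifacts:::pixel_grid()
  pol <- rnflartifacts:::disc_polar(a, grd$x, grd$y)
  arc <- matrix(0L, g$rows, g$cols)
  arc[pol$ang > 55 & pol$ang < 95 & pol$r > a$disc_radius & pol$r < 3] <- 2L
  regs <- extract_abnormal_regions(pmap_from_mask(arc, a), cfg)
  expect_equal(classify_artifact_type(regs), "arcuate")

  # temporal wedge hugging the disc and the maculo-papillary sector
  tq <- matrix(0L, g$rows, g$cols)
  tq[abs(pol$ang) < 35 & pol$r > a$disc_radius & pol$r < 3] <- 2L
  regs <- extract_abnormal_regions(pmap_from_mask(tq, a), cfg)
  expect_equal(classify_artifact_type(regs), "temporal_Q")

  # disjoint arcuate + temporal regions: both
  both <- arc; both[tq == 2L] <- 2L
  both[pol$ang >= 35 & pol$ang <= 55] <- 0L  # keep them disconnected
  regs <- extract_abnormal_regions(pmap_from_mask(both, a), cfg)
  expect_gte(length(regs), 2)
  expect_equal(classify_artifact_type(regs), "both")

  # a region that fails the temporal-disc condition cannot vote
  far <- matrix(0L, g$rows, g$cols)
  far[pol$ang > 55 & pol$ang < 95 & pol$r > 3 & pol$r < 4.5] <- 2L
  regs <- extract_abnormal_regions(pmap_from_mask(far, a), cfg)
  expect_equal(classify_artifact_type(regs), "none")
})

test_that("the midline rule, alone and combined with GCL+, follows region geometry", {
  a <- eye_anatomy()
  cfg <- rule_config(min_area_mm2 = 0)
  g <- scan_geometry()
  expect_equal(vertical_midline_rule(
    pmap_from_mask(matrix(0L, g$rows, g$cols), a), cfg), "negative")

  # RNFL arcuate stopping at the midline: negative alone
  rnfl <- block_mask(4.5, a$fovea_center[1] - 0.1, 3, 3.5)
  pm_rnfl <- pmap_from_mask(rnfl, a)
  expect_equal(vertical_midline_rule(pm_rnfl, cfg), "negative")
  # GCL+ abnormality continuing nasally, contiguous with the RNFL band:
  # the combined rule turns positive
  gcl <- block_mask(a$fovea_center[1] - 0.4, a$fovea_center[1] + 2, 3, 3.5)
  pm_gcl <- pmap_from_mask(gcl, a)
  expect_equal(vertical_midline_rule(pm_rnfl, cfg, gcl_pmap = pm_gcl),
               "positive")
  # a disjoint GCL+ patch does not help
  gcl_far <- block_mask(a$fovea_center[1] + 1, a$fovea_center[1] + 2, 6, 7)
  expect_equal(vertical_midline_rule(pm_rnfl, cfg,
                                     gcl_pmap = pmap_from_mask(gcl_far, a)),
               "negative")

  # rule nesting: positive implies the necessary condition
  band <- block_mask(4.5, a$fovea_center[1] + 2, 4.3, 4.7)
  pm_band <- pmap_from_mask(band, a)
  regs <- extract_abnormal_regions(pm_band, cfg)
  expect_equal(vertical_midline_rule(pm_band, cfg), "positive")
  expect_true(any(vapply(regs, temporal_disc_condition, logical(1))))
})

test_that("enlarging an abnormal mask never flips the spatial flags to false", {
  a <- eye_anatomy()
  cfg <- rule_config(min_area_mm2 = 0)
  withr::with_seed(21, {
    for (i in 1:10) {
      x0 <- runif(1, 3, 6); w <- runif(1, 1, 4)
      y0 <- runif(1, 2, 5)
      m_small <- block_mask(x0, x0 + w, y0, y0 + 0.4)
      m_big <- block_mask(x0 - 0.5, x0 + w + 1.5, y0 - 0.3, y0 + 0.7)
      rs <- extract_abnormal_regions(pmap_from_mask(m_small, a), cfg)
      rb <- extract_abnormal_regions(pmap_from_mask(m_big, a), cfg)
      if (length(rs) && length(rb)) {
        if (rs[[1]]$touches_temporal_disc)
          expect_true(rb[[1]]$touches_temporal_disc)
        if (rs[[1]]$crosses_midline)
          expect_true(rb[[1]]$crosses_midline)
      }
    }
  })
})

test_that("rule outcomes are invariant under OD/OS mirroring of the same eye", {
  model <- noise_reference_model(150, noise_sd = 3, seed = 5)
  g <- scan_geometry()
  a_od <- eye_anatomy(bundle_peak_angles = c(45, -75))
  a_os <- eye_anatomy(fovea_center = c(g$width_mm - 8.4, 4.5),
                      disc_center = c(g$width_mm - 3.9, 4.5),
                      laterality = "OS", bundle_peak_angles = c(45, -75))
  m_od <- synthesize_thickness_map(a_od, noise_sd = 0)
  m_os <- synthesize_thickness_map(a_os, noise_sd = 0)
  pm_od <- compute_pmap(m_od, model)
  pm_os <- compute_pmap(m_os, model)
  expect_equal(pm_os$percentile, pm_od$percentile, tolerance = 1e-9)
  cfg <- rule_config("red_or_yellow")
  expect_equal(vertical_midline_rule(pm_os, cfg), vertical_midline_rule(pm_od, cfg))
  expect_equal(classify_artifact_type(extract_abnormal_regions(pm_os, cfg)),
               classify_artifact_type(extract_abnormal_regions(pm_od, cfg)))
})
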