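# Shared fixtures and independent oracles for the test suite.

default_anatomy <- function(...) eye_anatomy(...)

# Constant-valued thickness map with given age (bypasses the simulator).
constant_map <- function(value, age = 50, anatomy = eye_anatomy(age = age)) {
  g <- scan_geometry()
  thickness_map(matrix(value, g$rows, g$cols), anatomy)
}

# A small reference model fitted to noiseless identical-anatomy maps plus
# independent pixel noise: the cheapest model that allows red pixels is
# avoided on purpose; tests that need red use n >= 150.
noise_reference_model <- function(n, anatomy = eye_anatomy(), noise_sd = 3,
                                  seed = 42, ages = NULL) {
  base <- synthesize_thickness_map(anatomy, noise_sd = 0)$values
  if (is.null(ages)) ages <- seq(40, 80, length.out = n)
  maps <- withr::with_seed(seed, lapply(seq_len(n), function(i) {
    a <- anatomy; a$age <- ages[i]
    agefac <- (1 - 0.002 * (ages[i] - 50))
    v <- pmax((base - 12) / 1 * agefac + 12 +
                matrix(rnorm(length(base), 0, noise_sd), nrow(base)), 0)
    thickness_map(v, a)
  }))
  fit_normative_model(maps)
}

# Brute-force 8-connected flood fill, the oracle for component labeling.
flood_fill_label <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      stack <- list(c(i, j))
      lab[i, j] <- cur
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (di in -1:1) for (dj in -1:1) {
          ii <- p[1] + di; jj <- p[2] + dj
          if (ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask) &&
              mask[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cur
            stack[[length(stack) + 1L]] <- c(ii, jj)
          }
        }
      }
    }
  }
  lab
}

# Hand-count confusion metrics oracle.
hand_confusion <- function(groups, positive, pos_set, neg_set) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(groups)) {
    if (groups[i] %in% pos_set) {
      if (positive[i]) tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (positive[i]) fp <- fp + 1L else tn <- tn + 1L
    }
  }
  list(TP = tp, FP = fp, TN = tn, FN = fn,
       sensitivity = 100 * tp / (tp + fn), specificity = 100 * tn / (tn + fp))
}

# Build a probability_map directly from a category matrix (field view, OD),
# for constructed-geometry tests of the region rules.
pmap_from_mask <- function(category, anatomy = eye_anatomy(),
                           thresholds = c(red = 1, yellow = 5)) {
  g <- scan_geometry()
  stopifnot(all(dim(category) == c(g$rows, g$cols)))
  structure(list(percentile = 50 - 49 * (category > 0),
                 category = category, anatomy = anatomy, view = "field",
                 od_frame = TRUE, layer = "RNFL", thresholds = thresholds),
            class = "probability_map")
}

# Rectangular block of "abnormal" pixels given in mm (field view, OD frame).
block_mask <- function(x0, x1, y0, y1, value = 2L, base = NULL) {
  g <- scan_geometry()
  m <- if (is.null(base)) matrix(0L, g$rows, g$cols) else base
  cols <- which((seq_len(g$cols) - 0.5) * g$dx >= x0 &
                (seq_len(g$cols) - 0.5) * g$dx <= x1)
  rows <- which((seq_len(g$rows) - 0.5) * g$dy >= y0 &
                (seq_len(g$rows) - 0.5) * g$dy <= y1)
  m[rows, cols] <- value
  m
}
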