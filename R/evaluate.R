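#' Visual-field record reliability
#'
#' A field is reliable iff false-positive and false-negative error rates
#' are strictly below 15\% and fixation losses strictly below 33\%.
#'
#' @param record A one-row data frame (or list) with \code{FP_rate},
#'   \code{FN_rate}, \code{fixation_loss_rate} in percent.
#' @return Logical.
#' @export
vf_reliable <- function(record) {
  record$FP_rate < 15 & record$FN_rate < 15 & record$fixation_loss_rate < 33
}

#' Abnormal 24-2 visual field (modified OHTS criterion)
#'
#' Abnormal iff the glaucoma hemifield test is outside normal limits and/or
#' the pattern standard deviation has p < 0.05 (or stricter).
#'
#' @param record A record with \code{GHT} in \{"within_normal",
#'   "borderline", "outside_normal"\} and \code{PSD_pcat} in \{"ns",
#'   "p<0.05", "p<0.01", "p<0.005", "p<0.001"\}.
#' @return Logical.
#' @export
ohts_abnormal_242 <- function(record) {
  record$GHT == "outside_normal" | pcat_at_most(record$PSD_pcat, 0.05)
}

#' Abnormal 10-2 visual field
#'
#' Abnormal iff MD and/or PSD has p <= 0.05.
#'
#' @param record A record with \code{MD_pcat} and \code{PSD_pcat}.
#' @return Logical.
#' @export
abnormal_102 <- function(record) {
  pcat_at_most(record$MD_pcat, 0.05) | pcat_at_most(record$PSD_pcat, 0.05)
}

# TRUE when the categorical p-value is at or below the given level.
pcat_at_most <- function(pcat, level) {
  vals <- c(ns = 1, `p<0.05` = 0.05, `p<0.01` = 0.01,
            `p<0.005` = 0.005, `p<0.001` = 0.001)
  v <- vals[as.character(pcat)]
  if (any(is.na(v))) stop("unknown p-category: ",
                          paste(unique(pcat[is.na(v)]), collapse = ", "))
  unname(v) <= level
}

#' Perimetric early-glaucoma classification (EG_VF)
#'
#' TRUE iff some run of three consecutive 24-2 records is reliable,
#' abnormal by the modified OHTS criterion, with the same non-none abnormal
#' hemifield across the three tests -- or the analogous condition holds for
#' the 10-2 series (abnormality by MD and/or PSD at p <= 0.05).
#'
#' @param series_242,series_102 Date-ordered data frames of visual-field
#'   records (may be empty).
#' @return Logical.
#' @export
classify_EG_VF <- function(series_242, series_102) {
  n242 <- if (is.null(series_242)) 0L else nrow(series_242)
  n102 <- if (is.null(series_102)) 0L else nrow(series_102)
  if (n242 < 3 && n102 < 3)
    stop("insufficient-data error: need at least 3 records on one pattern")
  run3 <- function(series, abnormal_fun) {
    if (is.null(series) || nrow(series) < 3) return(FALSE)
    ok <- vf_reliable(series) & abnormal_fun(series) &
      series$abnormal_hemifield != "none"
    hemi <- series$abnormal_hemifield
    for (i in seq_len(nrow(series) - 2)) {
      w <- i:(i + 2)
      if (all(ok[w]) && length(unique(hemi[w])) == 1) return(TRUE)
    }
    FALSE
  }
  run3(series_242, ohts_abnormal_242) || run3(series_102, abnormal_102)
}

#' Glaucoma severity stage from 24-2 mean deviation
#'
#' Standard severity bands: early (EG) for MD of -6 dB or better, moderate
#' (MG) strictly between -6 and -12 dB, advanced (AG) for -12 dB or worse.
#' Boundary values -6 and -12 are assigned to EG and AG respectively.
#'
#' @param MD_242 Mean deviation in dB.
#' @return "EG", "MG" or "AG" (vectorized).
#' @export
severity_stage <- function(MD_242) {
  ifelse(MD_242 >= -6, "EG", ifelse(MD_242 > -12, "MG", "AG"))
}

#' Eligibility filter
#'
#' TRUE iff best-corrected visual acuity is 20/40 or better (denominator
#' at most 40) and the spherical equivalent lies in [-6, +6] diopters.
#'
#' @param BCVA_denominator Snellen denominator (20/x).
#' @param spherical_equivalent_D Refraction in diopters.
#' @return Logical (vectorized).
#' @export
eligibility_filter <- function(BCVA_denominator, spherical_equivalent_D) {
  BCVA_denominator <= 40 &
    spherical_equivalent_D >= -6 & spherical_equivalent_D <= 6
}

#' Confusion metrics for a rule over labeled evaluations
#'
#' Counts rule-positive calls against ground-truth group membership and
#' derives sensitivity = 100 TP / (TP + FN) and specificity =
#' 100 TN / (TN + FP).
#'
#' @param evaluations A data frame with columns \code{group} and
#'   \code{positive} (logical rule outcome), or a list of per-eye lists
#'   with those elements.
#' @param positive_groups,negative_groups Character vectors of group labels
#'   forming the disease and healthy sets; they must not overlap, and every
#'   evaluation must fall in exactly one.
#' @return An object of class \code{confusion_metrics} with counts
#'   \code{TP}, \code{FP}, \code{TN}, \code{FN} and percentages
#'   \code{sensitivity}, \code{specificity} (unrounded).
#' @export
confusion_metrics <- function(evaluations, positive_groups, negative_groups) {
  if (length(intersect(positive_groups, negative_groups)) > 0)
    stop("configuration error: overlapping group sets")
  if (!is.data.frame(evaluations)) {
    evaluations <- do.call(rbind, lapply(evaluations, function(e)
      data.frame(group = e$group, positive = e$positive,
                 stringsAsFactors = FALSE)))
  }
  in_pos <- evaluations$group %in% positive_groups
  in_neg <- evaluations$group %in% negative_groups
  if (any(!(in_pos | in_neg)))
    stop("configuration error: evaluation group outside both sets")
  tp <- sum(in_pos & evaluations$positive)
  fn <- sum(in_pos & !evaluations$positive)
  fp <- sum(in_neg & evaluations$positive)
  tn <- sum(in_neg & !evaluations$positive)
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                 sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("confusion_metrics: TP %d FP %d TN %d FN %d | sens %.1f%% spec %.1f%%\n",
              x$TP, x$FP, x$TN, x$FN, x$sensitivity, x$specificity))
  invisible(x)
}

#' Artifact-frequency tabulator
#'
#' Per-group frequency of eyes whose map meets the glaucoma-like artifact
#' definition, and the taxonomy table of artifact types.
#'
#' @param groups Character vector of group labels, one per eye.
#' @param types Character vector of artifact types per eye ("none",
#'   "arcuate", "temporal_Q", "both").
#' @return A list with \code{by_group} (data frame: group, n, n_artifact,
#'   percent) and \code{taxonomy} (data frame of counts and percent of all
#'   eyes per type).
#' @export
tabulate_artifacts <- function(groups, types) {
  stopifnot(length(groups) == length(types))
  has <- types != "none"
  by_group <- do.call(rbind, lapply(unique(groups), function(gr) {
    sel <- groups == gr
    data.frame(group = gr, n = sum(sel), n_artifact = sum(has & sel),
               percent = 100 * sum(has & sel) / sum(sel),
               stringsAsFactors = FALSE)
  }))
  tax <- do.call(rbind, lapply(c("arcuate", "temporal_Q", "both"), function(tp)
    data.frame(type = tp, n = sum(types == tp),
               percent = 100 * sum(types == tp) / length(types),
               stringsAsFactors = FALSE)))
  list(by_group = by_group, taxonomy = tax)
}
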