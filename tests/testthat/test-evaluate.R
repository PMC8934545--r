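vf_rec <- function(FP = 5, FN = 5, FL = 10, GHT = "within_normal",
                   PSD = "ns", MD = "ns", hemi = "none", pattern = "24-2",
                   date = 1) {
  data.frame(test_pattern = pattern, date = date, MD = -1,
             MD_pcat = MD, PSD_pcat = PSD, GHT = GHT,
             FP_rate = FP, FN_rate = FN, fixation_loss_rate = FL,
             abnormal_hemifield = hemi, stringsAsFactors = FALSE)
}

test_that("reliability and abnormality criteria use the documented thresholds", {
  expect_true(vf_reliable(vf_rec(14.9, 14.9, 32.9)))
  expect_false(vf_reliable(vf_rec(15, 0, 0)))    # strict inequalities
  expect_false(vf_reliable(vf_rec(0, 15, 0)))
  expect_false(vf_reliable(vf_rec(0, 0, 33)))

  expect_true(ohts_abnormal_242(vf_rec(GHT = "outside_normal")))
  expect_true(ohts_abnormal_242(vf_rec(PSD = "p<0.05")))
  expect_true(ohts_abnormal_242(vf_rec(PSD = "p<0.01")))
  expect_false(ohts_abnormal_242(vf_rec()))
  expect_false(ohts_abnormal_242(vf_rec(GHT = "borderline")))

  expect_true(abnormal_102(vf_rec(MD = "p<0.05")))
  expect_true(abnormal_102(vf_rec(PSD = "p<0.05")))
  expect_false(abnormal_102(vf_rec()))
})

test_that("perimetric classification needs 3 consecutive same-hemifield abnormal fields", {
  ab <- function(hemi, FP = 5) vf_rec(FP = FP, GHT = "outside_normal",
                                      hemi = hemi)
  s3 <- rbind(ab("superior"), ab("superior"), ab("superior"))
  expect_true(classify_EG_VF(s3, NULL))
  # alternating hemifields fail the persistence requirement
  alt <- rbind(ab("superior"), ab("inferior"), ab("superior"))
  expect_false(classify_EG_VF(alt, NULL))
  # a normal visit breaks the run; a later run of three still qualifies
  seq5 <- rbind(ab("superior"), vf_rec(), ab("superior"), ab("superior"),
                ab("superior"))
  expect_true(classify_EG_VF(seq5, NULL))
  # unreliable abnormal fields do not count
  unrel <- rbind(ab("superior", FP = 20), ab("superior", FP = 20),
                 ab("superior", FP = 20))
  expect_false(classify_EG_VF(unrel, NULL))
  # the 10-2 pathway alone suffices
  s102 <- rbind(vf_rec(MD = "p<0.05", hemi = "inferior", pattern = "10-2"),
                vf_rec(MD = "p<0.05", hemi = "inferior", pattern = "10-2"),
                vf_rec(MD = "p<0.05", hemi = "inferior", pattern = "10-2"))
  expect_true(classify_EG_VF(rbind(vf_rec(), vf_rec(), vf_rec()), s102))
  expect_error(classify_EG_VF(s3[1:2, ], s102[1:2, ]), "insufficient-data")
  # prepending reliable-normal visits does not change the outcome
  expect_true(classify_EG_VF(rbind(vf_rec(), s3), NULL))

  # the simulator's patient series classify as perimetric glaucoma
  coh <- generate_cohort(list(groups = c(EG = 3), layers = character(0)),
                         seed = 2)
  for (eye in coh) {
    vf <- eye$vf
    expect_true(classify_EG_VF(vf[vf$test_pattern == "24-2", ],
                               vf[vf$test_pattern == "10-2", ]))
  }
})

test_that("severity stages and eligibility follow the clinical bands", {
  expect_equal(severity_stage(c(-3, -6, -9, -12, -15)),
               c("EG", "EG", "MG", "AG", "AG"))
  expect_true(eligibility_filter(20, 0))
  expect_true(eligibility_filter(40, -6))
  expect_false(eligibility_filter(50, 0))
  expect_false(eligibility_filter(20, -6.5))
  expect_false(eligibility_filter(20, 6.5))
})

test_that("confusion metrics match hand counts on random small splits", {
  # tallies at clinical-study scale
  ev <- data.frame(
    group = c(rep("HC", 254), rep("EG", 32)),
    positive = c(rep(TRUE, 2), rep(FALSE, 252), rep(TRUE, 24), rep(FALSE, 8)))
  cm <- confusion_metrics(ev, "EG", "HC")
  expect_equal(cm$FP, 2)
  expect_equal(round(cm$specificity, 1), 99.2)
  expect_equal(cm$sensitivity, 75)

  # perfect classifier
  ev2 <- data.frame(group = c("G", "G", "H"), positive = c(TRUE, TRUE, FALSE))
  cm2 <- confusion_metrics(ev2, "G", "H")
  expect_equal(c(cm2$sensitivity, cm2$specificity), c(100, 100))

  # property: random splits up to 10 eyes against the brute-force oracle
  withr::with_seed(9, {
    for (i in 1:40) {
      n <- sample(2:10, 1)
      groups <- sample(c("A", "B"), n, replace = TRUE)
      if (length(unique(groups)) < 2) groups[1:2] <- c("A", "B")
      positive <- runif(n) < 0.5
      got <- confusion_metrics(data.frame(group = groups, positive = positive),
                               "A", "B")
      want <- hand_confusion(groups, positive, "A", "B")
      expect_equal(got[c("TP", "FP", "TN", "FN")],
                   want[c("TP", "FP", "TN", "FN")], ignore_attr = TRUE)
      expect_equal(got$sensitivity, want$sensitivity)
      expect_equal(got$specificity, want$specificity)
    }
  })

  expect_error(confusion_metrics(ev2, "G", "G"), "overlapping")
  expect_error(confusion_metrics(ev2, "G", "X"), "outside both sets")
})

test_that("artifact tabulation reproduces printed-count arithmetic", {
  # counts as inputs: 254 healthy eyes, 13 arcuate / 5 temporal / 2 both
  groups <- c(rep("HC_norm", 200), rep("HC", 54))
  types <- rep("none", 254)
  types[1:8] <- "arcuate"; types[9:13] <- "temporal_Q"; types[14] <- "both"
  types[201:205] <- "arcuate"; types[206] <- "both"
  tab <- tabulate_artifacts(groups, types)
  hcn <- tab$by_group[tab$by_group$group == "HC_norm", ]
  expect_equal(hcn$n_artifact, 14)
  expect_equal(hcn$percent, 7)
  hc <- tab$by_group[tab$by_group$group == "HC", ]
  expect_equal(hc$n_artifact, 6)
  expect_equal(round(hc$percent), 11)
  expect_equal(tab$taxonomy$n, c(13, 5, 2))
  expect_equal(round(tab$taxonomy$percent), c(5, 2, 1))
})

test_that("report percentages recompute from the report's own counts", {
  cfg <- default_experiment_config()
  cfg$n_reference <- 25L
  cfg$groups <- c(HC = 4L, EG = 3L)
  cfg$artifact_rate <- c(HC = 0)
  cfg$use_gcl <- FALSE
  rep1 <- suppressWarnings(run_experiment(cfg, seed = 5))
  cm <- rep1$midline_rule
  if (cm$TP + cm$FN > 0)
    expect_equal(cm$sensitivity, 100 * cm$TP / (cm$TP + cm$FN))
  expect_equal(cm$specificity, 100 * cm$TN / (cm$TN + cm$FP))
  rep2 <- suppressWarnings(run_experiment(cfg, seed = 5))
  expect_identical(rep1$eyes$G_cpRNFL, rep2$eyes$G_cpRNFL)
  expect_identical(rep1$eyes$midline_positive, rep2$eyes$midline_positive)
  expect_error(run_experiment(list(groups = c(HC = 0)), 1), "config error")
})
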