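Package: rnflartifacts
Title: Glaucoma-Like Artifacts on Wide-Field RNFL Probability Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying glaucoma-like artifacts on optical coherence
    tomography (OCT) retinal nerve fiber layer (RNFL) probability maps. The
    package builds age-corrected per-pixel normative (percentile) maps from a
    healthy reference cohort, extracts connected abnormal regions and
    evaluates rule-based classifiers for them (the temporal-disc necessary
    condition, an arcuate/temporal-quadrant artifact taxonomy, and a vertical
    midline rule, including a combined RNFL + ganglion cell layer variant),
    computes global circumpapillary RNFL thickness on the 3.4-mm circle, and
    evaluates rule sensitivity and specificity on labeled cohorts. A
    synthetic wide-field (9 x 12 mm) thickness-map simulator with
    parameterized retinal anatomy (arcuate bundle trajectories, vessel
    ridges, papillomacular bundle, glaucomatous wedge defects) makes every
    stage testable without clinical scans.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    pracma,
    tiff,
    EBImage,
    igraph,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
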