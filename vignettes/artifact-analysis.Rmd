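---
title: "Glaucoma-like artifacts on RNFL probability maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glaucoma-like artifacts on RNFL probability maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `rnflartifacts`: what the
synthetic thickness-map generator emulates (and deliberately does not), how
the normative percentile map is defined, how the spatial decision rules are
operationalized, and the numerical conventions that make results
reproducible.

## The problem

Wide-field OCT probability maps flag pixels whose retinal nerve fiber layer
(RNFL) thickness is below the 1st ("red") or 5th ("yellow") percentile of an
age-corrected healthy reference. Because the *location* of the major
arcuate bundles and their accompanying vessels varies between healthy eyes,
a perfectly healthy retina can be red exactly where the reference
population carries its bundles — an arcuate artifact that mimics
glaucomatous damage. The package implements the full chain needed to study
this: a generative model of wide-field maps, normative percentile mapping,
region extraction with rule-based classification, circumpapillary metrics,
and cohort-level evaluation.

## Coordinate and view conventions

All maps live on a fixed 256 × 512 grid covering 9 × 12 mm (pixel pitch
0.0352 × 0.0234 mm); pixel `[i, j]` has its center at
`((j − 0.5)·dx, (i − 0.5)·dy)` with y increasing downward. Maps are
generated in *retina view* (row 1 = superior retina) and analyzed in *field
view* (vertical flip: top = superior visual field); left eyes are mirrored
horizontally into the right-eye frame on conversion, so every spatial rule
runs in a single frame. Both conversions are involutive and transform the
landmark metadata together with the grid. Angles are measured at the disc
from the disc-to-fovea axis (temporal = 0°), positive toward the superior
retina.

## The generator

The baseline template is a closed-form field over disc-centered polar
coordinates `(r, ψ)`. Every pixel is assigned the entry angle `θ0` of the
unique bundle trajectory through it, by inverting the angular decay map
`ψ = θ0 · exp(−c (r − r_d)²)` with `c = 0.03 /mm²` — a quadratic-spiral
course that bends each bundle toward the temporal raphe without ever
crossing it and leaves the papillomacular axis straight. The template sums:

- two arcuate bundle ridges (Gaussian in `θ0`, amplitude 140 µm, width 22°
  at the disc) centered on the eye's `bundle_peak_angles` (population
  ±65° ± 5°);
- a nasal ridge (85 µm, width 50°) and a papillomacular plateau
  (60 µm, perpendicular width 1.2 mm) that fades within 0.25 mm past the
  fovea;
- narrow vessel ridges (+30 µm, σ = 0.15 mm) that track each bundle at the
  eye's `vessel_offsets`;
- radial thinning away from the disc (e-fold 3 mm), a foveal pit
  (σ = 0.45 mm), a 12 µm measurement floor, and a linear age factor
  (−0.2 %/year around age 50).

Two structural choices matter for the artifact question. First, *bundles
rejoin a canalized common course*: an eye's entry-angle deviation tapers
off within ~2.5 mm of the disc. A displaced bundle therefore produces a
thickness deficit that is strong near the disc and vanishes peripherally —
whereas a glaucomatous wedge defect removes a fixed fraction of tissue
along entire trajectories, out to the scan edge. This is precisely the
structural dissociation the vertical midline rule exploits, and it is the
package's operationalization of the observation that artifact arcs hug the
disc while true arcuate damage sweeps past the fovea's vertical. Second,
*papillomacular amplitude variation expresses near the disc* and blends
into the tightly canalized perifoveal profile within ~1 mm of the fovea,
so congenital temporal thinning does not read as damage across the
midline.

Artifact mechanisms in healthy cohorts (probability `artifact_rate`, split
65/25/10):

- `displaced_bundle`: one major bundle (with its vessel) enters at
  65° − N(30°, 5°) toward the raphe — the far tail of the population
  distribution. The norm then expects bundle tissue where this eye has
  none, which reads as an arcuate red band at the typical bundle site.
- `thin_temporal`: the papillomacular amplitude scaled by U(0.35, 0.5) — a
  broad temporal-quadrant red region including the maculo-papillary
  sector.
- `both`: both mechanisms.

Patient defects are hard-edged wedges in entry-angle space (so the removed
fraction along affected trajectories is exactly `depth_fraction`): early
glaucoma draws width U(15°, 40°), depth U(0.3, 0.6) and a finite radial
extent U(4, 10) mm — a fraction of early defects are spatially limited and
terminate temporal to the fovea midline (~5.5 mm from the disc), which is
why the midline rule misses a share of early eyes while remaining near
perfect for worse damage; moderate glaucoma draws width
U(40°, 70°) × depth U(0.6, 0.8), advanced a combined arcuate +
diffuse-temporal wedge at depth U(0.8, 0.95), both at full radial extent; 24-2 mean deviation is drawn inside the
corresponding severity band and three reliable, hemifield-consistent
visual-field visits are attached per test pattern. Landmarks jitter only
slightly (fovea σ = 0.08 mm) because acquisition registers the scan on the
fovea; disc-fovea distance (4.5 ± 0.15 mm) and disc radius
(0.9 ± 0.07 mm) carry the anatomical variation. Measurement noise is
i.i.d. Gaussian (default σ = 3 µm, clipped at zero) — small against
~100 µm bundles.

What the generator does **not** emulate: speckle, shadowing and
segmentation failures (scan-quality artifacts are a different problem from
the anatomical artifacts studied here), B-scan-level physics, high myopia,
and spatially correlated biological noise. Passing tests on these cohorts
therefore show that the *rules* behave as designed under the stated
anatomy-variation model — not that the simulator reproduces every property
of clinical scans.

## The normative model and percentile map

`fit_normative_model()` fits, per pixel, ordinary least squares of
thickness on age over the reference cohort (slope fixed at zero with a
warning if the age span is under 10 years) and retains all reference
residuals as an empirical quantile table. `compute_pmap()` ranks an eye's
age-corrected residual by midrank:
`percentile = (1 + #{table < obs} + #{table = obs}/2) · 100/(n + 1)`,
so with n = 200 the attainable range is 0.5–99.5 and a "red" call
(percentile < 1) requires the observation to undercut essentially the
entire reference. No parametric tail assumption is made; this is robust at
n = 200 but means red pixels are impossible for references under ~100
eyes. Categories: red < 1, yellow < 5 (configurable; the 1%/5% convention
is the commercial standard). No spatial smoothing is applied by default —
smoothing changes region topology, and the rules below are topological.

Held-out calibration: for eyes drawn from the reference process with
independent pixel noise, the fraction of pixels below the 5th percentile
is 10/201 ≈ 4.98% by rank arithmetic; the acceptance suite checks the
empirical fraction against the binomial 95% interval around 5%.

## Region rules

Abnormal regions are 8-connected components of red (default) or red+yellow
pixels, discarded below 0.1 mm² (≈ 121 pixels — suppresses noise specks
that readers implicitly ignore), sorted by area.

- **Necessary condition** (`temporal_disc_condition`): the region
  intersects the annulus up to 1 mm outside the disc boundary, restricted
  to the temporal half-plane (the side of the disc containing the fovea).
  "Near" is qualitative in the source material; 1 mm is the package
  default and is echoed in every output.
- **Taxonomy** (`classify_artifact_type`): disc-centered sectors from the
  disc-fovea axis — temporal ±45°, superior arcuate (45°, 135°), inferior
  arcuate (−135°, −45°). *Arcuate* if a qualifying region has ≥ 50% of its
  area in an arcuate sector; *temporal_Q* if ≥ 50% in the temporal
  quadrant and it touches the maculo-papillary sector (the temporal wedge
  truncated at the fovea); *both* if both hold.
- **Vertical midline rule** (`vertical_midline_rule`): positive iff a
  qualifying region has pixels strictly nasal-field of the vertical line
  through the fovea, pixels temporal of it (contiguity across the line is
  inherited from connectivity), and ≥ 0.25 mm nasal extent (so one-pixel
  grazing does not fire the rule). With a GCL+ probability map supplied,
  components of the union of both abnormal masks are tested — an RNFL
  arcuate that stops at the midline can be carried across by contiguous
  macular GCL+ damage, which is what distinguishes a true early defect
  from an artifact when the RNFL map alone is ambiguous.

The reader-consensus step of the original workflow is replaced by these
deterministic rules; that is a deliberate operationalization, and the
red-only versus red-or-yellow choice (both phrasings occur in the source
material) is a configuration flag with red-only as default.

## Circumpapillary metrics

`extract_circle_profile()` samples the thickness grid by bilinear
interpolation at 256 equally spaced angles on the 3.4-mm-diameter circle
around the disc center, TSNIT order (temporal → superior → nasal →
inferior), in the OD frame; `global_cprnfl()` is the arithmetic mean. The
sample count matches the scan's B-scan count; a zero-width circle is used
(whether devices average over a band is unknown). `percentile_cutoff()`
uses midrank (type-6) interpolation, e.g. the 5th percentile of 1…100 is
5.05.

## Cohort evaluation

Reliability: false positives and false negatives < 15%, fixation losses
< 33% (strict). A 24-2 field is abnormal if GHT is outside normal limits
and/or PSD has p < 0.05; a 10-2 if MD and/or PSD has p ≤ 0.05. Perimetric
early glaucoma requires three *consecutive* reliable abnormal fields with
the same abnormal hemifield on either pattern. Severity bands from 24-2
MD: early ≥ −6 dB, moderate strictly between −6 and −12, advanced ≤ −12 —
the conventional bands; the boundary values −6/−12 are assigned to EG/AG
respectively (the source text's inequality signs are contradictory if read
literally, so the standard convention is implemented).
`confusion_metrics()` reports unrounded sensitivity = 100·TP/(TP+FN) and
specificity = 100·TN/(TN+FP).

## Problem sizes and numerical choices

The experiment driver defaults to the study design: a 200-eye artifact-free
reference for the model, 54 + 200 healthy study eyes at 11%/7% artifact
rates, and 32/12/18 EG/MG/AG patients; the detected artifact frequency on
healthy groups exceeds the injected mechanism rate by a few percent because
natural tails of the anatomy distributions also read as artifacts, as they
do in real normative cohorts. The acceptance suite runs scaled-down
cohorts (60-eye mechanism cohorts, a 254-eye taxonomy cohort, 500 oracle
grids, 100 000 calibration pixels) chosen so each block answers its
question with comfortable statistical margin; the reproduction script runs
the full-scale experiment but simulates GCL+ maps only for the patient
groups (its combined-rule quantity is a sensitivity) and sizes the
calibration check at 150 reference + 30 held-out eyes x 2 000 pixels. Determinism: every
stochastic step is seeded (`withr::with_seed`), cohorts are bit-for-bit
reproducible from (spec, seed), and reported percentages always recompute
from the reported counts. Connected components are labeled by
`EBImage::bwlabel` (4-connectivity) followed by merging of diagonally
adjacent labels via a label graph, giving the 8-connectivity the rules
assume; a brute-force flood fill serves as the independent oracle in the
tests.

## Known limitations

- The displacement distribution of artifact eyes is a free simulator
  parameter (the phenomenon's literature does not quantify it); the
  defaults express the mechanisms reliably at n = 200 normative
  resolution, and rates are configurable.
- The normative model corrects for age only; disc size or refraction
  corrections used by commercial devices are not modeled.
- The GCL+ model is a simple macular donut with hemifield defects — enough
  to exercise the combined midline rule, not a model of macular disease.
- Sensitivity and specificity measured on synthetic cohorts characterize
  the rules under this generative model; they are not clinical estimates.
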