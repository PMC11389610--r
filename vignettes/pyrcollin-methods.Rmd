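---
title: "Curvature-corrected neuron collinearity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curvature-corrected neuron collinearity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyrcollin)
```

## The measurement problem

Pyramidal neurons of the hippocampal cornu ammonis and subiculum orient
their apical axis roughly perpendicular to the pyramidal cell layer. A
population-level statistic of that alignment — collinearity — requires two
ingredients an external cell segmenter does not provide: a per-cell axial
orientation, and a correction for the fact that the layer itself bends, so
"perpendicular to the layer" corresponds to a different absolute angle at
every position. `pyrcollin` supplies both, plus the false-positive
filtering that segmentation output needs before any morphometry, and the
mixed-model machinery for comparing subregions.

All coordinates are 0-based pixels (x = column rightward, y = row
downward); every angle is reported in the mathematical convention
(counter-clockwise from +x with y pointing up), so the row axis is
sign-flipped before any `atan2`. Orientations are *axial* (defined modulo
180°) throughout; only the correction angle is directional (modulo 360°).

## Per-cell orientation

Each kept object is summarized by the ellipse with the same centroid and
second central moments as its pixel set, each pixel treated as a unit
square (adding 1/12 to the diagonal moments — this keeps the minor axis
positive even for one-pixel-wide objects and does not affect the
orientation, because the term is isotropic). The uncorrected orientation
`UncO` is the major-axis angle folded into [0°, 180°). Moment matching was
chosen over outline least-squares because it is the "fit ellipse"
convention of the common image-analysis tools this pipeline
interoperates with, and because moments are robust for filled blobs.

Near-circular objects have no meaningful axis; fits with
major/minor < 1.05 (configurable) are gated out of orientation statistics
but remain in the counts. The gate threshold is an addition of this
package: a 5 % axis-ratio excess corresponds to an angular standard error
of tens of degrees for typical soma sizes, so anything below it is noise.

## Curvature correction

Given a manually drawn centerline of the pyramidal layer (an ordered
polyline), each neuron's correction angle `CorrA` is the direction from
its centroid to the nearest point on the polyline (projections onto
segment interiors included; ties broken deterministically toward the
lowest segment index). The corrected orientation is

```
CoO = (CorrA − UncO + 90°) mod 180°
```

`CoO = 90°` means the major axis is parallel to the centroid-to-line
direction, i.e. locally perpendicular to the layer. Because `CoO` is
folded axially, measuring `CorrA` toward the line or away from it (180°
apart) gives the same `CoO` — neurons on either side of the centerline are
treated identically, which the test suite verifies as a property. A neuron
whose centroid falls exactly on the centerline has no defined direction to
it; the local centerline normal is substituted and the record flagged.

The defining property of the construction is rigid-motion invariance:
rotating the whole scene (mask and centerline together) changes `UncO` and
`CorrA` by the same amount, leaving every `CoO` unchanged up to
re-rasterization error. The acceptance suite measures this on a 200-neuron
arc scene over seven rotation angles (bound: < 2° per neuron for ≥ 20 px
objects).

## Collinearity measures

Two statistics summarize the `CoO` population of a partition or subregion:

* **Mean angular deviation** `dev = mean(min(|CoO − 90°|, 180° − |CoO −
  90°|))`, in [0°, 90°]: the average axial distance from perfect
  perpendicularity. It is anchored to the fixed 90° reference, not to the
  sample mean — the alternative reading (circular SD about the mean) is
  available behind a flag, but the reference-anchored form is the default
  because the 90° reference is what gives the statistic its anatomical
  meaning.
* **Axial circular variance** `var = 1 − R̄`, with `R̄` the mean resultant
  length of unit vectors at the *doubled* angles `2·CoO`. Doubling is the
  standard treatment for period-180° data; without it, diametrically
  opposite representations of the same axis would cancel. A raw-angle mode
  exists for replication of directional conventions; outputs are labeled
  with the mode used.

Subregion-level pooling is ambiguous between neuron-weighted and
partition-weighted means; `pooled_subregion_summary()` reports both.

## False-positive filtering

Four exclusion classes are applied in a fixed order with first-hit
attribution, per partition:

1. *extracellular*: mean grey (on the prepared, inverted image) strictly
   below the midpoint of the mean object grey and mean background grey;
2. size statistics (mean and SD of equivalent-circle diameter and of
   area) are computed over the survivors of rule 1 — computing them before
   rule 1 would let faint speckle corrupt them;
3. *too_small*: diameter < mean − 0.75 SD (glia, partial profiles);
4. *too_large_diameter*: diameter > mean + 1.75 SD;
5. *too_large_area*: area > mean + 1.75 SD (merged/overlapping somata).

Boundary equality is kept in all rules (the thresholds are written as open
deviations, and keeping the boundary is the conservative choice; it is
unit-tested with dyadic-exact constructions where mean and SD are floating-
point exact). "Diameter" is operationalized as the equivalent-circle
diameter `2·sqrt(area/π)`; the fitted-ellipse minor axis is available via
configuration. The grey threshold is computed per partition by default;
since `apply_filters()` accepts the threshold as an argument, it can
equally be computed once per slide and passed to every partition of that
slide.

Two consequences worth knowing. First, because the cutoffs scale with the
observed SD, the filter always trims roughly the lower quarter of a
unimodal size distribution — on contaminant-free synthetic scenes about
70–80 % of planted somata survive, which is the intended behaviour of the
size rules, not a defect (the kept fraction on real Nissl material is of
the same order). Second, with fewer than two survivors of the grey rule
the SDs are undefined; the size rules are then skipped with a warning
rather than silently applied.

## Slide-level normalization and subregion comparison

Angular deviations are heavily non-normal and heteroscedastic across
slides. Within each slide, observations are mapped to normal quantiles by
rank: `z = Φ⁻¹(r/(n+1))` with average ranks for ties (the `(r − 0.5)/n`
convention is available). The transform is rank-preserving and
slide-local, both verified as properties. A high `z` means the neuron
ranks among the highest angular deviations of its slide.

Subregions are compared with a linear mixed model on `z` — subregion as
fixed effect, random intercepts for case and slide (crossed by default;
nesting slide within case is a switch, since the sampling design reuses
the same anatomical levels across cases, which favours crossed) — and a
likelihood-ratio test against the intercept-only model with the same
random effects. Both fits use ML, not REML, because REML likelihoods are
not comparable across fixed-effect structures. Pairwise contrasts use the
single-step multiplicity adjustment based on the joint multivariate-normal
distribution of the contrast statistics, with a Bonferroni fallback; the
mode is recorded in the output.

## The synthetic-scene generator

`generate_scene()` emulates what the pipeline consumes: a curved lamina
(circle arc, sine wave, or line) with elongated somata placed at
stratified positions along the curve within a band of configurable width,
oriented along the local curve normal plus axial von Mises noise (sampled
by the Best–Fisher rejection algorithm on doubled angles). Defaults were
chosen once to emulate the tissue conditions: 20 µm somata at a 2:1 axis
ratio (2·√(ab) ≈ 14 µm equivalent diameter, the scale of human pyramidal
somata), a 40 µm layer band, 0.5 µm/px sampling, dark cells (grey 40) on a
light background (grey 220) with σ = 4 sensor noise, as in an inverted
Nissl render. Contaminants mirror the four false-positive classes: 6 µm
glia-like discs, merged doublets (two overlapping somata under one label,
about 1.9× the single-cell area), and faint 3-px speckle near background
intensity. Rendering is hard-masked — no antialiasing — so label masks are
exact and per-object truth (class, centroid, axial orientation, pixel
area, curve position) is bookkept bijectively. Triangle-shaped somata use
the apex-to-base-midpoint axis as true orientation, mirroring how manual
orientation lines are drawn from between the basal dendrites toward the
apical dendrite, folded to axial. Placement is collision-free with bounded
retries; an overcrowded specification raises an error rather than
degrading silently.

What the generator does **not** emulate: stain texture within somata,
partial-volume effects at 50 µm section thickness, segmentation errors
other than the four planted classes (e.g. boundary erosion), anisotropic
shrinkage, and spatial density gradients. Passing tests therefore
demonstrate correctness of the *post-processing* given a segmentation, not
of any segmenter, and transfer to tissue only to the extent that the
segmenter's output resembles clean filled blobs.

`generate_multilevel_dataset()` simulates the comparison design directly
at the observation level: additive subregion effects, crossed case and
slide intercepts, Gaussian residuals, truncation to [0°, 90°]. Its default
group structure is seven cases by five anterior–posterior levels,
mirroring the tissue study design the simulation stands in for. The
calibration experiments in the acceptance suite use 8 subregions,
σ_case = σ_slide = 2°, σ_residual = 8°, baseline 25° (the observed scale of
subregion mean angular deviations), with 2 observations per
subregion × case × slide cell (560 per replicate) for the null
calibration, and a 4° (= 0.5 residual SD) single-subregion shift with 11
observations per cell (385 per subregion) for power.

## Numerical choices and degenerate inputs

* Angle folding uses `%% 180`, which maps 180 to 0 exactly; axial
  distances use `min(d, 180 − d)`.
* Orientation is undefined for objects of fewer than 3 pixels or gated
  near-circular fits; such records carry `NA` and are excluded from
  orientation statistics, never silently assigned.
* A constant image cannot be contrast-stretched; it is inverted and
  returned with a warning.
* An all-zero label mask is valid (zero objects); masks with float values
  are rejected with a remediation hint, and labels are always relabeled to
  consecutive integers in raster order of first appearance so per-object
  tables have stable keys.
* Partition crops keep an object if and only if its centroid is inside
  the polygon — each neuron belongs to exactly one partition even when
  partitions share borders — and kept boundary-straddling objects retain
  all their pixels so their moments are unbiased.
* The external segmenter is invoked only through a subprocess adapter; if
  the tool is absent the adapter fails with instructions to use
  precomputed masks, and nothing downstream depends on it.

## Problem sizes used in the verification suite

The test and acceptance computations use scene sizes chosen to make the
geometry informative while keeping the whole suite desk-scale: 100-neuron
arcs for the perpendicular limit and noise tracking, a 200-neuron arc at
1 µm/px for rotation invariance, 1000 rendered ellipses for fit accuracy,
50 small random scenes for the filter partition property, and 500
simulated replicates for the null calibration of the mixed-model
inference (60 for power, where rejection is essentially certain).

## Known limitations

* The correction assumes a single-section (2-D) geometry; out-of-plane
  tilt shortens somata anisotropically and is not modelled.
* `dev` statistics feed the mixed model; `var` is descriptive only.
* The centerline is an input; the optional `draft_centerline()` helper
  (principal-axis binning of the kept-neuron point cloud) is a drafting
  aid, not a substitute for manual tracing, and fails on strongly
  re-entrant layers.
* With very small partitions (tens of objects), the per-partition SD
  estimates that drive the size filter are noisy; the reason codes remain
  auditable, but thresholds should be inspected via `thresholds_used`.
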