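---
title: "Measuring facet tropism from axial label masks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring facet tropism from axial label masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facetropism)
```

## The measurement model

The package measures facet joint orientation on one axial lumbar slice from a
four-class label mask (background, vertebral body VB, facet joints FJ,
posterior arch PA). The procedure assumes:

* the slice shows one vertebral level with both facet joints visible;
* the mask uses the radiological axial display convention, which this package
  pins explicitly: row 1 is anterior, rows increase posteriorly, and columns
  increase toward the patient's left;
* both facet joints share the single FJ class; laterality is derived
  geometrically, not from labels.

Pixel indices are 0-based and converted to physical millimetres by
elementwise multiplication with the pixel spacing; every landmark and
distance the package reports is in mm.

### Landmarks

* **VBC** is the centre of mass of the largest VB connected component
  (4-connectivity throughout; diagonal contact never merges regions).
* **SP** is the PA pixel with the maximal posterior coordinate. Ties are
  broken by the column closest to VBC's column, then by the lower column
  index, so results are bit-reproducible.
* The **facet endpoints** come from the two largest FJ components. Each
  component is assigned left or right by the sign of its centroid's lateral
  offset from the VBC→SP line; if both fall on one side the slice is rejected
  (`LateralityError`) rather than silently mismeasured. Within a component
  the anterior/posterior endpoints are the pixels with extreme projection
  onto the VBC→SP axis, ties broken by greater absolute lateral offset, then
  lower column index.

Two readings of "anterior/posterior end points" are possible: extremes along
the image row axis, or along the anatomical VBC→SP axis. The package uses the
anatomical axis, which is robust when the midline is tilted and coincides
with the row reading when it is not. The VB centre of mass is computed over
the full region, not its boundary.

### Angles and tropism

With `u = PF − AF` and `v = SP − VBC`, each side's angle is
`acos(|u·v| / (|u||v|))` in degrees — the acute angle in [0°, 90°]. The
absolute value makes the measure independent of the (arbitrary) direction of
the facet line; reversing AF and PF changes nothing. Asymmetry is the signed
difference `thetaL − thetaR`; facet tropism at threshold `t` is
`|thetaL − thetaR| > t` (strict). The graded scheme bands use exclusive
lower and inclusive upper bounds, so an asymmetry of exactly 7° grades as
mild, not moderate.

### Cohort summaries

Per (level, sex) cell the summary reports mean and SE for the right angle,
left angle, the per-subject pooled average `(thetaL + thetaR)/2`, and the
asymmetry magnitude `|thetaL − thetaR|`. Conventions chosen where the
reporting format leaves room:

* SE uses the sample SD (n − 1 denominator) divided by `sqrt(n)`; a
  single-record cell reports SE 0 with a warning.
* The asymmetry column summarises the *magnitude*, which is the only reading
  consistent with published per-level values being several times larger than
  the near-zero mean of the signed distribution. The signed distribution is
  preserved separately (with the fractions inside ±10° and ±20°).
* Printed tables round half-even to 2 decimals; stored values are unrounded.

## The phantom generator

The phantom exists so that every stage is testable without clinical data. It
renders the minimal anatomy the landmark rules rely on: an elliptical VB
anteriorly on the midline, a PA ring segment around the spinal canal with a
spinous-process strip protruding posteriorly, and two FJ strips placed
posterolaterally at the requested angles. Defaults emulate the target
acquisition: 512×512 pixels at 0.35 mm spacing (~180 mm field of view);
smaller rasters keep the same physical field by scaling the spacing.
Ground-truth landmarks are stored in continuous millimetre coordinates
*before* rasterization, and the truth angles are exactly recomputable from
them through the angle formula.

Design points that took iteration:

* **Facet tips.** The extracted endpoint is a pixel with extreme projection
  onto the midline axis. Flat-ended strips bias that pixel toward a corner
  (error ≈ atan(width/length) ≈ 8–12°), and tapered tips disconnect under
  4-connectivity. The shipped shape is a constant-width core plus a
  supercover polyline whose final leg runs parallel to the midline axis, so
  the extreme pixel sits in the single column containing the analytic
  endpoint. The remaining error is pure lateral quantization, bounded by half
  a pixel per endpoint.
* **Midline pinning.** The phantom's lateral midline sits on a pixel-column
  centre. On even-sized grids the image centre falls *between* columns; the
  SP tie-break would then land half a pixel off the midline and tilt the
  reference axis by ~atan(s/2 / 26 mm), which at coarse rasters dominates the
  error budget. With the pinned midline the mirror property (flipping the
  mask negates the asymmetry) holds to 1e-14.
* **Error budget vs. resolution.** The quantization bound
  `s(cosθ + sinθ)/L` radians (pixel size `s`, facet length `L = 20` mm)
  gives a measured worst-case of ~0.7° at 512 px and ~1.3° at 256 px over the
  30–55° grid; 1.5° is *not* attainable at 128 px (measured up to ~3.2°),
  which is why angle-recovery tests run at 512/256 px while 128 px is used
  for the training smoke scale, where only a 3° mean matters.
* **Geometry verification.** The generator checks its own contract — every
  region non-empty, pairwise disjoint and non-touching, VB/PA one connected
  component each and FJ exactly two — and raises `GeometryError` otherwise,
  so impossible parameter combinations fail loudly.
* **Images.** The optional grayscale image is per-class constant intensity
  (bg 0.2, FJ 0.5, VB 0.7, PA 0.9), Gaussian blur (0.5 mm), additive Gaussian
  noise (SD 0.03). That is sufficient to exercise a segmentation model;
  Rician noise, bone texture, and pathology (osteophytes, joint degeneration)
  are deliberately absent — a green end-to-end test establishes that the
  machinery is correct, not that any model generalises to clinical MRI.

The cohort sampler draws angles from truncated normals (support [5°, 85°])
whose means match the per-level, per-sex reference statistics shipped in
`cohortReference()`; per-subject SDs are recovered as `SE × sqrt(n)` from the
subgroup sizes (female n = 678, male n = 599, reconstructed from the
published prevalence count/percentage pairs).

## Segmentation metrics

* Class surfaces are pixels of the class with at least one 4-neighbour
  outside it; the image border counts as outside. Distances are Euclidean
  between pixel centres, scaled by the spacing — no sub-pixel surface model.
* ASD is the mean of the two directed average surface distances.
* HD95 is the 95th percentile, with linear interpolation between order
  statistics (R quantile type 7), of the *pooled* multiset of both directed
  distance sets. Conventions differ across toolkits (some take the max of
  per-direction percentiles); the pooled variant is symmetric by
  construction and is what the brute-force oracle in the test suite verifies
  to 1e-9.
* Empty classes: if a class is empty in both masks, Dice and IoU are defined
  as 1 with a warning (so ablation tests are well-defined); empty in exactly
  one, 0. Surface distances require the class on both sides and otherwise
  raise `EmptySurfaceError`, which pair-level evaluation propagates rather
  than silently NA-filling.

## Rater agreement

* The Bland-Altman variant is nonparametric: median bias and 2.5th/97.5th
  percentile limits of agreement (again quantile type 7), appropriate when
  the differences fail normality. The difference direction is fixed as first
  series minus second and recorded in the result.
* `fracWithinRef` is the fraction of slices with `|asymmetry|` strictly below
  the clinical reference value, reported per rater over the common slices.
* The "coefficient of determination" is the squared Pearson correlation,
  equal to OLS R² in simple regression.
* The normality gate runs Shapiro–Wilk and a Kolmogorov–Smirnov test against
  a normal with the sample mean/SD, flagging the nonparametric path if either
  rejects at α = 0.05. Shapiro–Wilk's implementation limit is n = 5000;
  larger samples are reduced to 5000 evenly spaced order statistics. The KS
  p-value with estimated parameters is conservative; it is used only as a
  gate, not as a calibrated test.

## The desk-scale trainer

The training harness reproduces the protocol — Generalized Dice Loss,
participant-level k-fold splits (all of a participant's slices stay in one
fold), Adam with weight decay, early stopping and model selection on
validation macro IoU, and the named augmentations (random tone curve, gamma,
brightness, contrast, horizontal flip, Gaussian blur; parameters are package
defaults, documented in `defaultAugmentations()`) — around a deliberately
small model: per-pixel features (z-scored intensity, three Gaussian-blur
scales, midline distance, row position, radial distance) feeding a linear
softmax or one-hidden-layer tanh MLP (`"mlp16"` default). The clinical-scale
encoder-decoder is out of scope; the architecture string keeps the harness
agnostic.

The loss is
`GDL = 1 − 2 Σ_l w_l Σ_n r_ln p_ln / Σ_l w_l Σ_n (r_ln + p_ln)` with
`w_l = 1/(Σ_n r_ln)²`; classes absent from the reference get weight 0 and the
denominator carries a 1e-12 guard. Two numerical choices matter in practice:

* **Prior-informed initialisation.** Output biases start at the log class
  frequencies of the learning set. With inverse-squared-volume weights the
  gradient reaching a near-zero-probability channel of a large class is tiny,
  and a channel born dead can stay dead for the whole desk-scale budget.
* **Deterministic restarts.** Even so, roughly one in seven initialisations
  converges to a local optimum with one class unlearned (observed stuck for
  40+ epochs). `trainSegmenter()` therefore retries from a fresh,
  seed-derived initialisation stream (up to 3 attempts) when the best
  validation IoU stays below 0.9, keeping the best run — an application of
  the protocol's validation-IoU model-selection rule, and fully reproducible
  under the configuration seed.

The `"desk"` preset (2 folds, ≤15 epochs, batch 2, Adam lr 0.05, weight decay
1e-4) was fixed after a stability sweep on development phantoms; the
`"protocol"` preset records the full-scale protocol values (5 folds, 200
epochs, patience 20, batch 6, lr 1e-4) for documentation and clinical-scale
use.

## Pipeline semantics

`runPipeline()` preserves the *semiautomatic* design: which slice represents
each level is an input (the metadata CSV), never inferred. Per-slice failures
at any stage are logged to `exclusions.csv` with their reason and excluded —
never silently dropped — and the run aborts if more than half the slices of
a stage fail. The manifest records seeds, stage row counts and exclusion
counts; with a fixed seed, outputs are byte-identical across runs.

## Known limitations

* Everything is 2-D and single-slice: no 3-D surfaces, no multi-slice fusion
  per level, no volume phantoms.
* The phantom's geometric simplicity means phantom-trained models say nothing
  about clinical segmentation accuracy; published cohort-scale figures
  require the original (non-public) imaging data and are explicitly not
  reproduced here.
* Landmark extraction is pixel-level by design; at coarse rasters the angle
  quantization floor (see the error budget above) dominates and cannot be
  reduced without sub-pixel boundary modelling, which is out of scope.
* Associations between facet tropism and spinal disorders are analysis-level
  questions outside this package's remit.
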