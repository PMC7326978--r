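---
title: "Berry phenotyping from instance masks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Berry phenotyping from instance masks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(berryfield)
```

`berryfield` turns per-berry instance segmentations of blueberry branch
images into breeding-relevant traits and scores the segmentations
themselves. This vignette is the package's own account of the methods:
what is computed, under which conventions, why each open choice was made
the way it was, and what the synthetic test bed does and does not show.

## Coordinate and mask conventions

All coordinates are 0-based with x rightward and y downward, matching
common annotation tools. A mask is a logical `height x width` matrix; the
pixel with integer coordinates `(x, y)` occupies the unit square
`[x, x+1] x [y, y+1]` and has its center at `(x + 0.5, y + 0.5)`.

Polygons are rasterized by the **pixel-center rule**: a pixel belongs to
the polygon iff its center is inside (even-odd rule, half-open scanlines).
This makes areas reproducible — an axis-aligned square with corners
(10,10)–(20,20) rasterizes to exactly 100 pixels — and two polygons
sharing an edge tile the plane without double coverage.

## The three traits

For one view (one image of a branch):

* `N_b` — the number of detected instances. Only *visible* berries can be
  detected in a 2D image; no amodal completion is attempted.
* maturity — `N_m / N_b`, the mature-labeled fraction. Undefined (an
  error, not 0) when `N_b = 0`.
* compactness — `A / A_b`, where `A` is the **union** area of all
  instance masks and `A_b` the area of the minimum-area rotated rectangle
  enclosing them. The union counts pixels once: predicted masks of
  touching berries routinely overlap by a few pixels, and summing areas
  would double-count them.

A branch sample is imaged from five views covering 360°; the sample trait
is the unweighted arithmetic mean of the per-view values (no view is
privileged). Per-view rows are retained in the output CSV alongside one
`view = "mean"` row per sample.

### The minimum-area rectangle

`A_b` uses the smallest enclosing rectangle over *all* orientations, so
compactness does not change when the same branch is photographed at a
different angle — an axis-aligned box would. The optimum is found by the
rotating-calipers property (the minimal rectangle is flush with a convex
hull edge), and the hull is taken over **member-pixel corners**, not
centers, so the rasterized masks are geometrically contained in the
reported rectangle. The unit tests verify the area against a brute-force
0.01°-step angle sweep and check rotation invariance to 1e-6 relative.

One representational wrinkle: a rectangle's long side may lie at any
angle in [0, 180), so "w ≥ h" and "angle of the w-side in [0, 90)" cannot
both hold in general. The canonical `angle` reported is the axis-pair
orientation (long-side direction modulo 90°), which is what equality
tests need; the exact long-side direction is kept in `long_axis` and used
when corners are reconstructed.

## Objective maturity from Hue

Visual maturity annotation is inconsistent — similar-colored berries get
different labels from different annotators. The objective classifier uses
color instead:

1. The instance mask is eroded by a Euclidean disk of radius 10 px
   (default), dropping the boundary band where background and neighboring
   berries contaminate the color. Erosion is computed from the distance
   transform (a pixel survives iff its distance to background exceeds the
   radius), with pixels beyond the frame counting as background.
2. Hue is computed from RGB on the 0–180 half-degree scale, ignoring
   saturation and value, which makes the decision robust to the varying
   outdoor illumination the ratio-based Hue cancels.
3. The berry is **mature** iff more than half of the surviving pixels
   have Hue strictly inside (0, 30) ∪ (150, 180) — the red-to-purple
   range of ripe fruit. Green immature berries sit near (35, 100).

Two defensive choices: boundary Hues exactly at 0, 30, 150 or 180 are
*not* mature (the thresholds are strict inequalities as stated); and if
erosion would erase a small berry entirely, the original mask is used and
flagged, so every berry still receives a decision. The majority rule is
the package's own choice — the underlying histogram method does not fix
an aggregation rule — and is the natural reading of "which color does
this berry mostly show".

## Evaluating segmentations

Matching follows the COCO convention: predictions are processed in
descending confidence order (ties broken by larger IoU, then stable input
order) and each takes the unmatched ground truth of the same class with
the highest mask IoU, provided that IoU reaches the threshold. Per class
and threshold, `TP + FN` equals the number of ground truths and
`TP + FP` the number of predictions — asserted as a test invariant.

Average precision accumulates precision–recall points along the pooled
score-sorted detection list, monotonizes precision from the right, and
integrates over all recall increments (all-point AP rather than 11-point
sampling — the modern default and the direct reading of "average
precision across all recall values"). mAP is the mean of per-class APs
over {mature, immature}; per-class averaging was chosen so that failures
on the rarer class are not hidden by class imbalance. A class absent from
the ground truth is excluded with a warning. The suite checks AP against
an exhaustive prefix-enumeration oracle on small scenes.

Mean IoU (mIOU) averages the IoU of **matched pairs only**, measuring
mask shape quality independently of detection quality; with no matches it
is undefined rather than 0.

### Error taxonomy

Four error modes are tallied after matching at the primary threshold
(default 0.5), using a secondary floor (default 0.1) to decide what
"overlaps" means. In priority order, each instance consumed once:

1. **one-as-two** — a ground truth overlapped at ≥ floor by two or more
   unmatched predictions whose union reaches the primary threshold;
2. **two-as-one** — an unmatched prediction overlapping two or more
   ground truths at ≥ floor each;
3. **partial** — an unmatched ground truth with exactly one overlapping
   prediction in [floor, primary);
4. **missed** — an unmatched ground truth with no overlap at the floor.

The taxonomy is geometric, so its matching is class-agnostic (a berry
fragmented into two correctly-shaped pieces is a geometry error whatever
the labels say). The floor value is a package choice: low enough to
register genuine associations, high enough that incidental pixel overlap
between neighbors does not count.

## Count calibration

A single 2D view systematically undercounts a branch: berries hidden
behind others cannot be segmented. The correction is ordinary least
squares of ground truth on the detected count,
`truth = a + b · detected`, fitted pooled and per cultivar, with
in-sample R² and RMSE (no train/test split — the fit is a description of
the bias, not a predictive claim). The regression direction maps detected
to true count, which is the direction a user applies; on synthetic data
with planted undercount the fitted slope exceeds 1, recovering the hidden
fraction. Groups with fewer than three samples are skipped with a
warning; an all-constant detected vector is rejected (undefined slope),
and a constant truth vector yields slope 0 with R² defined as 0.

## The synthetic test bed

The generator emulates the study conditions: branch samples of 5–25
berries in 1–4 clusters, five views per branch, partial occlusion,
mature/immature classes separable by Hue, an artificial (uniform)
background. Berries are disks placed around cluster centers; a random
z-order makes the visible mask of each berry its disk minus the union of
disks in front of it, so partially occluded berries can have disconnected
visible masks (kept as one instance — exactly the situation that produces
partial detections in real imagery). Views of one branch share the berry
set (count, radii, labels, colors, cluster count) and re-sample
placements and z-orders independently, which exercises multi-view
aggregation without modeling true 3D rotation.

Default parameters, chosen once as realistic for branch close-ups at
320×320 px: berry radius 22 ± 3 px, mature Hue uniform over
(2, 28) ∪ (152, 178), immature over (40, 95), saturation 0.55–0.9, value
0.45–0.9, color noise sd 0.02 in RGB, overlap intensity 0.3 (centers may
approach to 0.7 of the sum of radii). The placement sampler widens a
cluster gradually when it saturates, and rejects a scene only if a berry
cannot be placed at all.

The perturbation engine reproduces each detection-error mode at a
controlled per-instance rate: *drop* (missed), *split* into two pieces
separated by a gap strip (one-as-two; the gap keeps each piece below IoU
0.5 with its berry, as a real fragmented detection would be), *merge*
with the nearest neighbor into the convex hull of both visible masks
(two-as-one; the hull is the single blob a segmenter would emit — a bare
union of two disjoint masks would paradoxically match the larger berry
at IoU ≥ 0.5 and disappear as an error), *jitter* translation (partial at
large shifts), and *relabel* (annotation noise). Unperturbed detections
keep the exact ground-truth masks with scores in [0.9, 1]; perturbed ones
score in [0.5, 0.9).

Everything is bit-reproducible from `(params, seed)`; the caller's RNG
state is restored afterwards.

### What passing synthetic tests does and does not show

The generator validates the *measurement layer*: geometry, color logic,
matching, metrics, aggregation, calibration algebra, format round-trips.
It does not validate detection of real berries — disks have no specular
highlights, bloom, pedicels, leaves, or soft mask boundaries, and
"views" are statistical re-draws rather than projections of one 3D
arrangement. Quantities that depend on a trained segmenter and field
imagery (validation-set mAP of a real model, cultivar trait tables)
cannot be reproduced by this package and are not claimed.

## Problem sizes and numerical choices

The test suite and the acceptance script run the study-shaped design —
104 branch samples × 5 views (520 images) — for the closure checks, with
smaller dedicated fixtures elsewhere: 50 clean scenes for the Hue
agreement check, 20 seeds per error mode for the taxonomy dominance
check, 20-sample datasets for evaluation under a mixed perturbation
load. These sizes give stable statistics while keeping a full run in
minutes on one core.

Tolerances: rectangle-vs-sweep agreement to 0.1% (the sweep's 0.01° grid
limits it); disk compactness to 0.01 of π/4 (rasterization of the disk
boundary); erosion of a rasterized disk to 3% of the analytic annulus;
AP to 1e-12 of the enumeration oracle (same arithmetic, different
algorithm); OLS coefficients to 1e-9 of the closed-form normal equations.

Degenerate inputs are rejected with clear errors rather than coerced:
polygons with fewer than 3 distinct vertices, IoU of two empty masks,
maturity or compactness of an empty view, mean IoU with no matches, AP
for a class with no ground truth, fits with under 3 points or constant
detected counts.

## Known limitations

* Compactness is defined at branch level; sub-branch (per-cluster)
  compactness is out of scope.
* The berry-count trait counts visible instances; the calibration
  regression, not the counter, carries the burden of occlusion.
* The Hue classifier assumes the 0–180 half-degree Hue convention; Hue
  histograms are aggregated by majority only.
* VIA export writes full (amodal) circular outlines for synthetic ground
  truth, while detection JSON carries the visible masks; the two serve
  different consumers (annotation editing vs. evaluation).
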