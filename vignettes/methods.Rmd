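---
title: "Quantifying 3D microglial morphology: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D microglial morphology: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(microglia3d)
```

## The problem

Retinal microglia shift from a ramified, surveillance morphology to an
amoeboid, phagocytic one as they activate. Quantifying that shift in
post-mortem wholemount retina requires segmenting individual IBA-1-labelled
cells in 3D confocal z-stacks — where bright vasculature bleeds into the
IBA-1 channel, cells touch, and manual annotation of thousands of cells is
impractical — and then reducing each cell to a small set of interpretable
shape descriptors (volume, convex-hull solidity, circularity, axis ratio),
its CD68 lysosomal content, and per-field count densities, which are finally
compared between donor groups.

`microglia3d` implements that whole chain: a three-class random-forest voxel
classifier on a multi-scale filter bank, watershed instance segmentation,
3D/2D morphometrics, CD68 colocalization, the gated two-sample statistics
and the group × CD68 two-way ANOVA — plus a synthetic stack generator with
exact ground truth, because donor images are not publicly available and
every stage needs a quantitative oracle.

## Voxel classification

The classifier discriminates `microglia`, `vasculature` and `background`
per voxel. Features are the raw intensity plus six filter families —
Gaussian smoothing, Laplacian of Gaussian, Gaussian gradient magnitude,
difference of Gaussians, structure-tensor eigenvalues, Hessian-of-Gaussian
eigenvalues — each at scales sigma = 0.3, 0.7, 1.0, 1.6, 3.5, 5.0 and 10,
for 71 features per voxel.

Conventions worth stating once:

* **Sigma units.** Scales are in voxel units, isotropic in index space,
  even though voxels are anisotropic (0.156 × 0.156 × 1 µm at the reference
  acquisition). This mirrors the convention of interactive voxel-
  classification tools; an optional correction (`anisotropy_correction`)
  scales the axial sigma by `dx/dz` but is off by default.
* **Two-scale filters.** The structure tensor uses an inner (gradient)
  scale of `0.5 * sigma` per outer scale — the tool convention is not
  published, so one documented rule keeps the feature count fixed. The
  difference of Gaussians at `sigma_i` is `G(sigma_{i+1}) - G(sigma_i)`,
  with `1.6 * sigma` closing the last pair.
* **Boundaries.** All filters use symmetric reflection, so border cells are
  not biased by zero padding.
* **Eigenvalues** are sorted descending, making features rotation-
  consistent.

The forest (ranger, 100 trees by default, probability mode) is trained on
sparsely labelled voxels only — the features of unlabeled voxels are never
materialized. Labeled voxels are sorted canonically before fitting so the
model is invariant to annotation order; training and prediction are fully
deterministic given the seed. Prediction runs in row chunks with results
identical to whole-stack prediction.

The simulated annotation protocol matters: when background labels are drawn
only from far-field voxels, the PSF halo around each cell is ambiguous to
the forest, the Otsu-thresholded probability mask dilates by 10–20% and
per-cell volumes inherit that bias. `sample_sparse_labels()` therefore
draws half of its background labels from the ≤ 1.5 µm shell just outside
objects — the in-silico analogue of the corrective workflow in which
annotators paint object borders explicitly after inspecting a live
prediction. With boundary labels present, the mask-to-truth volume ratio
sits near 1.00–1.03 on validation scenes.

## Instance segmentation

The post-processing chain is: smooth the microglia probability (Gaussian,
sigma = 1 voxel) → Otsu threshold (256-bin histogram, exhaustively
maximized between-class variance) → remove voxels with vasculature
probability ≥ 0.5 → Sobel gradient magnitude of the binarized mask as the
watershed elevation → marker-based watershed → size filter (drop instances
below 100 µm³) → optional expert accept/reject review.

Design choices where the procedure is underdetermined:

* **Markers.** Regional maxima of the Gaussian-smoothed (sigma = 2 voxels)
  Euclidean distance transform, computed with physical (anisotropic)
  spacing. Two refinements make this robust on ramified cells: a marker
  must sit at distance ≥ 2.5 µm from the mask boundary (above the thickest
  process radius, below the smallest soma radius, so seeds form in somas
  and never on processes), and markers closer than 5 µm keep only the
  strongest. Without the distance floor, distance-transform ridges along
  thick processes seed spurious instances and fragment cells.
* **Tie-breaking.** The Sobel elevation of a binary mask is flat (zero)
  across the entire interior, so the order in which equal-elevation voxels
  flood decides the split. Flooding is first-in-first-out within equal
  elevation (a deterministic insertion counter), which grows all markers at
  the same rate and places the boundary near the geometric midline of a
  neck. A strict index-order tie rule was rejected: on a flat plateau it
  lets the lowest-indexed marker sweep nearly the whole component.
* **Connectivity** is 26-connected in 3D and 8-connected in 2D throughout.
* **Orphan components** (mask components that receive no marker) become
  instances of their own rather than holes in the partition, so the labels
  always partition the mask exactly; the size filter then removes specks.
* **Sobel** gradients are taken in index space (no spacing compensation),
  matching common toolchain practice.

## Morphometry conventions

Per-cell records carry 3D metrics (volume, convex-hull volume, solidity)
and z-projection 2D metrics (area, perimeter, hull area/perimeter,
solidity, convexity = hull perimeter / perimeter, circularity =
4π·area/perimeter², minor/major axis, axis ratio). Three conventions fix
the numbers:

* **Hulls are taken over voxel/pixel corner points**, not centers. A convex
  digitized solid then achieves solidity exactly 1, and solidity, 2D
  solidity and convexity are provably ≤ 1. The price is a half-voxel
  outward inflation of the hull: an 8 µm digitized sphere scores solidity
  ≈ 0.84 / 0.91 / 0.95 at 1 / 0.5 / 0.25 µm pitch, approaching 1 as the
  pitch shrinks. Comparisons between cells measured at the same pitch are
  unaffected.
* **Perimeter.** The outer boundary of each 8-connected component is traced
  over pixel centers (Moore neighborhood), polygonalized into maximal
  straight runs — a run extends while its centers fit inside a straight
  strip narrower than one pixel — and corrected by +4 pixels (the Minkowski
  perimeter of the half-pixel square each center carries). This estimator
  is exact on every axis-aligned rectangle (a 10 × 10 px square has
  perimeter 40 px and circularity π/4 exactly) and lands within ~1% of 2πr
  on digitized disks, so circularity is comparable across shapes; a raw
  staircase boundary would misstate a disk's perimeter by ~29%. Interior
  holes are not traced, and area counts true mask pixels only; the
  isoperimetric bound (circularity ≤ 1) then holds on every mask the test
  suite generates.
* **Axis lengths** come from the eigenvalues of the second central moment
  matrix of pixel centers with the `1/12`-pixel variance correction,
  scaled to the moment-equivalent ellipse (length = 4·√λ). A square then
  has axis ratio exactly 1 and a 4:1 digitized ellipse ≈ 0.25.

Degenerate single-voxel/pixel ROIs use the unit cube/square conventions
(solidity 1, circularity π/4) and are flagged. Count densities are reported
in both field conventions: cells/mm² of lateral field and cells/mm³ of
stack volume.

## CD68 colocalization

The CD68 channel is thresholded over the voxels inside segmented cells
(speckle outside cells cannot contribute to per-cell volumes; a global
scope is available). Because the PSF smears each punctum into a dim halo, a
single Otsu threshold keeps the halo and overestimates punctum volume by
roughly 1.5–1.7× under the simulator's default optics. The default
`otsu_midpoint` method therefore runs Otsu a second time inside the
first-pass foreground (separating halo from core) and thresholds at the
midpoint of the two passes — an approximation to the half-intensity
boundary criterion that recovers blurred-object volumes with little bias
(0.95–1.03× in the validation suite). On noiseless data both rules
coincide exactly.

A cell is CD68⁺ when its CD68 volume reaches two voxels' physical volume —
one bright voxel can be noise; the threshold is configurable. The per-cell
record carries the CD68 volume, the CD68/IBA-1 volume ratio and the flag;
stack summaries report the CD68⁺ proportion in percent.

## Statistics

Single-factor comparisons use the normality-gated rule: Shapiro–Wilk on
each sample at alpha = 0.05 (the gate level is a package choice; the
source procedure does not state one); if both pass, a classical
equal-variance Student's t (Welch behind a flag), otherwise a two-sided
Mann–Whitney U — exact by full enumeration whenever the samples are
tie-free and `n·m ≤ 2000`, the normal approximation with tie and continuity
corrections otherwise. The branch taken is always recorded in the result.
The unit of analysis is the caller's declaration: per-cell values for size
and shape metrics, per-stack (per-subject) values for count densities and
CD68⁺ proportions.

Two-factor comparisons (group × CD68 status) use a Type-II
sums-of-squares two-way ANOVA — the design is unbalanced whenever CD68⁻
cells are rare, and Type II is the conventional choice when the omnibus
procedure's SS type is unstated — followed by the four pairwise contrasts
of interest (across groups within each CD68 stratum, across strata within
each group) with Bonferroni-multiplied p-values capped at 1. Stars follow
the reporting convention `*` ≤ 0.05 through `****` ≤ 0.0001.

## The synthetic-data generator

Because no donor stacks are deposited, every stage is validated against a
simulator whose ground truth is exact:

* **Cells** are an axis-aligned ellipsoidal soma plus 2–6 tubular processes
  grown as persistent random walks (step 0.75 µm, direction jitter 0.35).
  An `amoeboid` parameter in [0, 1] moves soma volume share between 0.65
  and 0.95 of the cell at fixed total volume, spanning the
  ramified-amoeboid spectrum; by default both study groups draw it from the
  same range, so there is no built-in shape effect — matching the finding
  that shape metrics do not separate the groups.
* **Volumes** are gamma-distributed (CV 0.3) and renormalized so the sample
  mean equals the requested group mean exactly; group defaults are 1085 µm³
  (control) and 1754 µm³ (AD), the reported machine-segmentation group
  means. Voxelization (center-inside rule) loses a few percent on thin
  processes, which is why the realized-mean contract is ±10%.
* **CD68**: 90% of cells receive 1–8 soma-confined puncta of radius
  0.5–1.5 µm (the AD default doubles the punctum count, following the
  direction of the reported CD68-load increase, not its magnitude).
* **Vessels** are wavy tubes (radius 2–4 µm) that fluoresce into the IBA-1
  channel by default, reproducing the confound that motivates the
  vasculature class; their geometry and brightness are free parameters, as
  no quantitative description exists to anchor them.
* **Optics and noise**: separable Gaussian PSF (sigma 0.3 µm lateral, 1 µm
  axial), Poisson shot noise at 0.2 photons per intensity unit and Gaussian
  read noise (sd 10) on a background of 100 and cell signal of ~500 —
  modest-SNR confocal conditions. Everything is seed-controlled;
  identical parameters and seed reproduce the stack bit for bit.
* **Ground truth** is the un-blurred voxelization; voxel ownership is
  first-come by cell index, vessels claim only cell-free voxels, and
  puncta are clipped to their own cell, so the labels partition the
  foreground with no overlap.

What the simulator does **not** emulate: depth-dependent attenuation,
spectral crosstalk, spatially varying background, hyper-ramified or rod
morphologies, microglia touching vessels along extended interfaces, and
the between-donor variability of real tissue. Passing the recovery suite
therefore demonstrates that the chain is correct and well-calibrated on
controlled data — not that its absolute accuracy transfers to donor
imagery.

## Problem sizes and validation design

The validation suites run desk-scale crops: 160 × 160 × 32 voxels at
0.5 × 0.5 × 1 µm (an 80 × 80 × 32 µm field holding 30 cells) for the
segmentation-recovery suite — ten scenes plus an eleventh used only to
train the classifier — and 128 × 128 × 28 voxels for the end-to-end
pipeline checks. The generator equally produces the full reference
geometry (2048 × 2048 px at 0.156 µm/px) when asked. Statistical checks
simulate at the reported group parameters (means, SEM-derived standard
deviations and group sizes) with lognormal per-cell volumes, matching the
long-tailed distributions seen in machine segmentation; the null
calibration of the gated test uses 2000 replicates.

## Known limitations

* The watershed treats each connected mask component with its markers
  independently; two cells whose somas genuinely interpenetrate (closer
  than the marker separation) merge.
* Perimeter, and hence circularity and convexity, depend on the stated
  boundary convention; absolute values from other toolchains (staircase,
  Crofton or smoothed-contour estimators) are not directly comparable,
  though group contrasts are.
* CD68 volumes depend on the thresholding convention; absolute lysosomal
  volumes are convention-bound in the same way.
* The classifier is trained per imaging regime; a model trained on the
  simulator's contrast statistics is not expected to transfer to real
  stacks without retraining on sparse labels from those stacks.
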