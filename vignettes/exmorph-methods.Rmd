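---
title: "Quantifying axon architecture in expansion-microscopy volumes"
author: "exmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying axon architecture in expansion-microscopy volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exmorph)
```

## The measurement problem

Protein-retention expansion microscopy (ProExM) embeds tissue in a
swellable gel and physically enlarges it roughly fourfold, so that
diffraction-limited light-sheet imaging resolves individual dopamine
axons in the striatum. A 3D convolutional segmentation network (of the
TrailMap family) turns each imaged volume into a per-voxel axon
probability map. `exmorph` implements everything downstream of that
map: turning it into a binary mask, reducing the mask to three global
numbers per image — axon **volume fraction**, skeleton **length
density**, and mean axon **radius** — and converting those numbers from
post-expansion image space back to pre-expansion tissue units. The
package also estimates the linear expansion factor itself from paired
pre-/post-expansion snapshots, quantifies patch (striosome) versus
matrix fluorescence in 2D projections, and implements the optical
fractionator estimator of total neuron number.

Because no public volumes accompany this workflow, validation is built
on synthetic phantoms with exact ground truth, generated by the
package itself and exercised by the test suite and
`scripts/acceptance.R`.

## Segmentation post-processing

Two parameters, both exposed and both defaulted to the standard
values:

* **threshold** (default 0.7, dimensionless): a voxel is foreground
  exactly when its probability is *strictly greater* than the
  threshold. A uniform volume at 0.7 therefore thresholds to empty.
* **minimum component size** (default 256 voxels): connected
  components with *strictly fewer* voxels are removed; a 256-voxel
  component survives. Components touching the volume border are kept
  — per-image densities are reported without border correction.

Connectivity for "component" is not dictated by the procedure text, so
it is a parameter (6, 18 or 26) defaulting to 26: thin curvilinear
axons traverse diagonal voxel steps, and face-connectivity would
fragment them. The labelling kernel is a deterministic scan-order
breadth-first search, and the test suite checks it exactly against a
brute-force flood fill over random volumes for all three
connectivities.

## The three morphometric measures

**Volume fraction** is foreground voxels over total voxels; voxel
spacing cancels, so it is identical in image and tissue space and is
exact on ground-truth masks by construction.

**Skeletonization** uses 6-subiteration directional thinning in the
Lee style: border voxels of each face direction in turn are deleted if
they are simple points, with line endpoints preserved and candidates
re-checked sequentially, so topology is provably preserved and the
result is deterministic. Simple points are recognised with the
Malandain–Bertrand characterization (exactly one 26-connected
foreground component in the 26-neighbourhood, and exactly one
6-connected background component in the 18-neighbourhood touching a
face neighbour) — equivalent to the usual Euler-table formulation but
verifiable by direct computation rather than by transcribed lookup
tables. No pruning of short branches is applied.

**Armature length.** Skeleton voxels are joined into a minimum
spanning forest of their 26-adjacency graph with physical
centre-to-centre edge weights. Summing those raw steps, however,
systematically overestimates oblique structures: the digital medial
axis of a tube that is not axis-aligned wobbles laterally by a voxel,
and the zigzag adds 5–16% of spurious length (we measured this on
straight capsules of known length). Calibrated chamfer weights would
repair random orientations at the cost of a −10% bias on axis-aligned
paths. Instead, the armature length is measured after one pass of tree
Laplacian smoothing of the node positions (weight 0.45 toward the
neighbour mean; endpoints and branch points anchored). Axis-aligned
paths are unchanged; on a calibration basket of primitives with known
centerline length (an axial bar, straight oblique capsules of radius
2–6 in random directions, tortuous single tubes) the mean bias is
−0.8% with a worst case under 6%. The raw step sum remains available
via `skeletonLength(x, raw = TRUE)`. **Length density** divides this
length by the physical image volume.

**Mean radius** evaluates an exact anisotropy-aware Euclidean distance
transform (Felzenszwalb–Huttenlocher lower-envelope algorithm per
axis, with per-axis spacing) at every skeleton voxel and averages,
pooling all components, with no half-voxel correction. On digital
cylinders of radius 2–6 the interior-slice mean lands within 0.25
voxels of the true radius.

**Tissue units.** With linear expansion factor $f$, lengths divide by
$f$, so the mean radius maps as $r_\mathrm{tissue} = r_\mathrm{image}/f$;
the reference volume shrinks by $f^3$, so length density maps as
$\rho_\mathrm{tissue} = \rho_\mathrm{image} \cdot f^2$; the volume
fraction is dimensionless and unchanged. Successive conversions
compose multiplicatively, so applying $f$ then $1/f$ is an exact
involution. Both image- and tissue-space values are always reported so
either convention can be audited.

Two conventions the source procedure leaves open are handled
explicitly: spacing anisotropy is honoured throughout (a
`assumeIsotropic` switch reproduces a voxel-unit variant), and the
per-image radius is the mean over skeleton voxels pooled across
components (not a per-component mean of means).

## Expansion-factor estimation

The estimator recovers the similarity transform
$x' = s\,R\,x + t$ between a pre- and a post-expansion image of the
same field:

1. scale-invariant keypoints from a difference-of-Gaussians pyramid
   (3 intervals per octave, base blur 1.6 px), with quadratic
   sub-pixel refinement, contrast and edge rejection;
2. a 4×4×8 gradient-orientation descriptor sampled in each keypoint's
   scale- and rotation-normalized frame;
3. Lowe ratio-test matching (0.75) of descriptors;
4. a RANSAC similarity fit over match pairs (3 px reprojection
   threshold, minimum 10 inliers, iteration cap 2000, fixed seed)
   followed by least squares on the inliers.

In the complex parameterization $z' = \alpha z + \beta$ the scale is
$|\alpha|$, which equals the square root of the determinant of the
linear block; reflections cannot arise. The ratio, threshold and
inlier settings are conventions, not reconstructions of the original
analysis, and are configurable via `siftParams()`. Degenerate inputs
(blank images, too few keypoints, matches or inliers) raise a classed
`expansionEstimationError` carrying diagnostics — never a silent
number. On analytic blob textures resampled under known transforms
(scales 2–4.5, rotations to 30°) the recovered scale is within 0.2%
and reciprocal runs multiply to 1 within 0.1%. `summarizeFactors()`
reports mean ± SEM across estimates; with $n = 1$ the SEM is reported
as 0 with an explicit `semDefined = FALSE` flag to keep tabular output
numeric.

## Patch/matrix analysis and stereology

Compartment analysis works on max projections with paired
integer-labelled ROI masks (patch label $k$ pairs with matrix label
$k$, mirroring the practice of drawing a patch ROI and moving a copy
into the matrix). The per-pair statistic is the ratio of mean
intensities — not the mean of pixel ratios — and pairs with zero
matrix mean are excluded with a warning count. Per-pair values are
always returned so any downstream aggregation (per section, per
animal) can be applied. `patchAreaFraction()` reports the union area
of patches over a region.

The optical fractionator estimator is
$\hat N = \sum Q^- \times \frac{1}{ssf} \times \frac{1}{asf} \times \frac{1}{tsf}$
with section sampling fraction $1/\text{interval}$, area sampling
fraction $\text{frame}/\text{grid tile}$, and thickness sampling
fraction $\text{dissector}/\text{thickness}$. Defaults follow the
standard midbrain design (every 6th section, 60×60 µm² frame, 150 µm
grid, 10 µm dissector); the mounted section thickness is measured at
the microscope and must be supplied, which also means published totals
cannot be reproduced without it. The guard zone (2 µm) is recorded as
metadata only — it does not enter the estimator algebra.

## Synthetic phantoms: what they emulate and what they do not

`generateAxonPhantom()` draws persistent random walks (unit steps,
direction perturbed by Gaussian noise scaled by a tortuosity parameter
in [0, 1]) and rasterizes each as a capsule: every voxel within the
tube radius of the centerline polyline. Capsule ends matter: the
medial axis of a capsule terminates at the polyline endpoints, so
thinning recovers the full ground-truth length rather than eroding
flat tube ends. Walks start on a face of the interior margin box
heading inward, emulating axon segments that traverse the imaged cube;
stubs shorter than max(10 µm, 4 radii) are rejected because a squat
capsule has no line-like medial axis. Non-overlap is enforced by
rejection sampling (100 retries per axon, with a separation guard of
one diagonal voxel so distinct tubes can never become 26-connected);
placement failures are reported by warning. Foreground probability is
fixed at 0.95 over a 0.2 background so the 0.7 threshold cleanly
separates signal, emulating a confident network output without
modelling one. Per-axon random substreams derive from the master seed,
so adding axon $n+1$ leaves axons $1..n$ bit-identical. Defaults: 64³
voxels (the working cube size of the segmentation networks these maps
emulate), isotropic 1 µm spacing, 10 axons, radius 3 voxels,
tortuosity 0.3, noise SD 0.05.

The phantoms deliberately do **not** simulate optical point-spread
blur, light-sheet striping, gel distortion fields, or the textured
uncertainty of real network output. Passing parameter-recovery tests
therefore demonstrates that the measurement chain is unbiased on
geometry it can represent exactly — it does not certify performance on
real tissue, where segmentation error dominates.

`generateExpansionPair()` renders an analytic Gaussian-blob texture
and evaluates the same analytic field under the exact similarity
transform (rotation about the image centre), so the pair is related by
a machine-precision transform with no interpolation artifacts;
`generateCompartmentImage()` places non-overlapping elliptical patches
(semi-axes 5–9% of the image side) with paired matrix ROIs translated
clear of all patches.

## Numerical choices and degenerate inputs

* Integer TIFFs rescale by dtype maximum (255, 65535), never by
  per-image maximum, so a threshold means the same thing across
  images; float samples are clipped to [0, 1]. Spacing is supplied
  explicitly, never parsed from TIFF tags.
* Axis order is fixed (z, y, x) with TIFF page index as z.
* Empty masks yield an all-zero result flagged `empty`; empty
  skeletons yield radius 0 with an `empty` attribute rather than NaN.
* Result serialization writes 17 significant digits so CSV/JSON
  round-trips reproduce doubles exactly.
* `runPipeline()` records per-item failures and continues, fails only
  if every item fails, and is byte-identical across re-runs under a
  fixed seed (the consensus sampler is the only stochastic step).

## Known limitations

* Directional thinning is order-sensitive: permuting the array axes of
  the same mask can change skeleton-derived metrics by a few percent
  (volume fraction is exactly invariant). The suite pins this at 3% on
  a representative phantom.
* Tube tips still lose up to ~2 voxels of skeleton at each end on
  thick tubes; with the study-scale tube lengths this is inside the
  10% length-recovery envelope, but very short, very thick structures
  will read short.
* The expansion estimator assumes a global similarity transform; it
  does not map expansion isotropy across the field of view and does
  not handle reflections (they are reported as failures).
* Problem sizes used by the validation suite — 64³ phantom volumes,
  20-phantom recovery panels, 128-px pre-expansion textures — were
  chosen as the smallest sizes at which the study conditions are
  faithfully represented.
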