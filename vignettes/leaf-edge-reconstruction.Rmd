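---
title: "Curve-based 3D leaf edge reconstruction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curve-based 3D leaf edge reconstruction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Point-based multiview reconstruction (SfM/MVS) represents a plant as an
unstructured point cloud. For leaves this is a poor fit at exactly the place
where much of the morphology lives: the edge. Point clouds leave the edge
position implicit, and a gap in the cloud may be a real hole in the lamina or
just a reconstruction deficiency. `leafedge3d` instead reconstructs each leaf
edge *as a curve*: a closed periodic B-spline in 3D, one loop for the outer
margin and one per hole.

The inputs are per-view leaf instance masks (label images; in practice from an
instance segmentation model, here also from the built-in renderer) and known
3x4 camera projection matrices (in practice from SfM). All world units are mm
and all image units px throughout.

## Pipeline

1. **2D edges.** Each instance's contours are traced on the pixel boundary
   (marching squares at level 0.5, sub-pixel vertices) and split into
   overlapping fragments with arc length in `[l_min, l_max]` and cyclic
   overlaps of at least `tau_overlap` px. Fragments are the unit of matching.
2. **Leaf correspondence.** Instances are per-view labels; physical leaves are
   recovered by DBSCAN-clustering the sparse 3D cloud, removing the points
   hidden from each camera (spherical-flip hidden point removal), projecting
   the survivors onto the masks, and assigning every (view, instance) to the
   cluster that lands the most points on it. Ties and untouched instances stay
   unassigned and are excluded from reconstruction.
3. **Curve sketch.** For camera pairs whose centres subtend at most `b_max`
   degrees at the mean camera position, each source fragment maps through the
   fundamental matrix to an epipolar band in the paired view; overlapping
   fragments of the same leaf form pair hypotheses; per-point epipolar
   intersections are triangulated (homogeneous DLT). Every reconstructed
   fragment is reprojected into the remaining views; a view supports it when
   at least `tau_v` percent of its points land within `tau_d` px of that
   view's edges. Fragments supported by fewer than `ceiling(tau_t * m)` views
   are discarded, then points individually supported by fewer than `tau_p`
   views are dropped.
4. **Closed B-spline fit.** Surviving points are pooled, separated into loops,
   ordered by polar angle in the loop's PCA plane, and fit per coordinate by
   linear least squares against a closed periodic B-spline basis.

## The closed B-spline basis

The curve is `f(l) = w b(l)` on the periodic domain `l in [0, 1)`, with `n-1`
coefficients per coordinate. The basis has `n-k-1` plain uniform B-spline
functions of degree `k` plus `k` wrap-around entries that sum basis `i` with
basis `i-(n-1)`. Pairing entries `n-1` apart is only consistent with `n-1`
uniform intervals on the period (knot spacing `1/(n-1)`), which is how the
design matrix is built; rows then sum to one exactly and the curve is
`C^{k-1}` across the seam. A conventional period-`n` spline would instead
carry `n` coefficients; the difference is one interval of resolution and has
no practical consequence at the working `n = 16` (or `n = 64` for highly
detailed shapes). Degree defaults to cubic (`k = 3`).

The polar-angle parameterization assumes loops are star-shaped about their
planar centroid after projection to the PCA plane. This is the main known
weakness: deeply lobed outlines can fold back in angle, and sparse angular
coverage makes the least-squares fit rank-deficient — reported as an
ill-conditioned-fit error carrying the largest parameter gap rather than
silently extrapolating. Collinear loop points are likewise an explicit error.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `l_min`, `l_max` | 40, 100 (at 1920 px width) | px | fragment length range; scale with image width (`default_sim_params()`) |
| `tau_overlap` | 15 (at 1920) | px | minimum cyclic overlap of consecutive fragments |
| `b_max` | 30/40/60 for 32/64/128 views | deg | maximum camera pairing angle |
| `tau_v` | 80 | % | fraction of a fragment's points that must be near edges for a view to support it |
| `tau_d` | 11 (at 1920) | px | support distance |
| `tau_t` | 0.5 | fraction of m | support threshold; the precision-recall sweep and guideline choose it |
| `tau_p` | `ceiling(0.5 * ceiling(tau_t * m))` | views | per-point support floor |
| `cap` | 10 | hypotheses | per-band hypothesis cap |
| tangency angle | 15 | deg | source points nearly tangent to their epipolar line, and candidate-side near-tangential intersections, are dropped |
| band dilation | 2 | px | tolerance added to the epipolar band for rasterisation error |
| `n`, `k` | 16, 3 (holes: `max(8, n/2)`) | — | closed B-spline intervals and degree |

Decisions worth recording:

* **`tau_t` as a ratio.** The support threshold is interpreted as a fraction
  of the total image count `m` and converted by `ceiling(tau_t * m)`, while
  support is counted over the `m - 2` views excluding the fragment's own
  pair. At `tau_t = 1` the bar is therefore unreachable by construction; the
  sweep grid tops out there deliberately.
* **`tau_p` default.** No published value exists for the point-level floor;
  half the fragment-level requirement is conservative and exposed as a flag.
* **Correspondence ambiguity.** When an epipolar line crosses a candidate
  fragment more than once, the branch is chosen by continuity: matched arc
  positions along the candidate should advance roughly like the arc
  positions along the source fragment, so dynamic programming selects the
  assignment minimising the total deviation from that isometric advance
  (both traversal orientations are tried). A greedy nearest-to-previous walk
  fails exactly where the candidate's projection folds back across the
  epipolar pencil; the global path does not. The tangency exclusion (15 deg)
  applies on both sides: source points nearly tangent to their own epipolar
  pencil, and source points whose line touches the candidate tangentially,
  are dropped. Fragments bounded by `l_max` keep fold regions short, which
  is the regime this rule is designed for; a chain that still goes wrong is
  caught by the reprojection-support filter.
* **Holes pair with holes.** A hole contour in one view is never hypothesised
  against an outer contour in another: hole and outer loops are separated in
  2D before matching, which both prunes a large ghost family and mirrors the
  practice of separating holes and edge before reconstruction.
* **Loop grouping.** Outer-pool points are grouped by DBSCAN with
  `eps = 0.08 x` bounding-box diagonal (largest cluster = the outer edge);
  hole-pool points use a fixed 3 mm radius. Ring-camera geometry
  systematically under-supports the top and bottom arcs of small holes
  (epipolar tangency), leaving gaps of a couple of mm that the radius must
  bridge while staying below the inter-hole spacing. Stray hole clusters
  under 2 percent of the pool are reported and discarded.
* **Precision/recall orientation.** Precision is the fraction of
  ground-truth samples with a reconstructed point within 30 mm and recall the
  fraction of reconstructed points with ground truth within 30 mm — kept in
  this (unconventional) orientation deliberately, with `swap = TRUE`
  available. The optimal threshold is the largest `tau_t` among those with
  maximal recall subject to precision above 0.99; if nothing clears 0.99 the
  grid minimum is returned, flagged.
* **Guideline regression.** The optimal thresholds are regressed on the
  occlusion index with Bayesian ridge regression (evidence maximisation,
  weak Gamma hyperpriors); the working lines are the predictive mean,
  mean − 0.25 SD and mean − 0.5 SD. The regression is univariate in OI; leaf
  area, camera noise and image count enter as qualitative adjustments only.
* **Empty reconstructions.** Precision and recall of an empty fragment set
  are defined as 0 to keep sweep curves total.

## The synthetic scene generator

The generator defines the study conditions and replaces external assets:
analytic planar leaf outlines (ovate base curve; cosine lobes or serration;
circular holes subtracted) triangulated by ear clipping; plants of eight
leaves with areas log-spaced over 312-3366 mm^2, placed around a vertical
stem with golden-angle azimuths and seeded jitter (horizontal uniform in
±33.33% of the leaf bounding box, vertical in −14.28%..+14.29%, rotation in
±10°); 32/64/128 cameras evenly spaced on a cylinder, aimed at the plant,
with optional isotropic Gaussian centre noise (σ ∈ {0, 1, 3} mm, orientation
re-aimed after perturbing — the minimal reading of positional camera error);
occluder pillars (none/thin/thick = 5/20 mm radius cylinders between ring
and plant); z-buffered label masks rendered analytically (scanline polygon
fill with ray-plane depth, ray-cylinder pillars); and an area-uniform
labeled point cloud standing in for the SfM sparse cloud.

Masks are rendered from the noise-free cameras; reconstruction uses the
noised rig, emulating imperfect SfM estimates against real images. The
default image size is 640x480 with fragmentation lengths and `tau_d` scaled
linearly from their 1920-width values, which keeps a full 8-leaf, 32-view
scene within seconds and the end-to-end single-leaf benchmark within about a
minute on one CPU; the tests and the acceptance script run at exactly these
sizes.

What the generator does **not** emulate: mask prediction errors (masks are
exact), SfM point-cloud artifacts and background points, leaf curvature
(laminae are planar), texture/colour (the colour-based clustering used for
real plants in contact is out of scope — DBSCAN stands in everywhere), wind
or growth. Passing tests therefore demonstrate the geometric machinery, not
robustness to segmentation noise.

## Worked example

```{r example}
library(leafedge3d)

scene <- make_scene(scene_spec(list(leaf_spec(1500)), n_views = 32L,
                               rng_seed = 3L))
bundle <- reconstruct_scene(scene)
print(bundle)

# sweep the support threshold and pick the working value
sk <- bundle$leaves[[1]]$sketch
pr <- sweep_support_threshold(sk, scene$true_edges[[1]][[1]])
optimal_support_threshold(pr)
```

## Numerical notes and limitations

* Triangulation is homogeneous DLT via SVD with row balancing; exact on
  noise-free input, and degenerate geometry (identical centres, points at
  infinity) errors out explicitly.
* The fundamental matrix comes from the known projection matrices through the
  epipole construction (no estimation), normalised to unit Frobenius norm;
  epipolar residuals on exact correspondences sit at machine precision.
* Edge support uses a Euclidean distance transform of the rasterised per-leaf
  contours (one per view, computed view-major and discarded), so support
  lookups are O(1) per point at `tau_d` in px.
* The discrete Frechet distance is exact dynamic programming (vectorised
  over anti-diagonals) on uniformly resampled polylines; for closed curves
  it is minimised over traversal direction and a nearest-point-anchored
  window of cyclic starts. Open-curve comparisons use the working 1 mm
  spacing; closed-curve comparisons default to 1/400 of the perimeter
  (capped at 1 mm, floored at 0.1 mm), because the discrete distance cannot
  resolve differences below about half the sampling step and desk-scale
  reconstructions are accurate to a few tenths of a mm.
* Hidden point removal degenerates when the cloud is (near) coplanar as seen
  after spherical flipping; the implementation then warns and treats all
  points as visible rather than failing.
* Serrated margins are averaged out at the working fragment lengths, apex
  regions of very elongated leaves lose fragment coverage, and more than
  three or four holes degrade hole separation — the reported loop counts and
  fit failures make these cases visible instead of masking them.
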