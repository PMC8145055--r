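---
title: "Measuring fixation-pin migration from CT-derived point clouds: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring fixation-pin migration from CT-derived point clouds: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pinmigrate)
```

## Overview

`pinmigrate` measures how femoral-neck fixation pins have moved between two
CT-derived 3D models of the same patient. The central difficulty is that
the two scans are acquired in different scanner poses, so the models live
in different coordinate systems. The package's answer is the classic
rigid-reference construction: a partial femur — cropped below the femoral
head, whose position the fracture itself can change — is a structure that
is essentially unchanged over the recovery period, so the rigid transform
aligning its follow-up cloud onto its postoperative cloud is exactly the
change of scanner pose. Applying that transform to the follow-up pin
clouds places both epochs of each pin in one frame, where displacement and
rotation can be measured directly.

All coordinates and lengths are in millimetres; transforms act on column
vectors as $x \mapsto Rx + t$ with $R$ a proper rotation
($R^\top R = I$, $\det R = +1$, both enforced to $10^{-9}$), and
composition is "outer after inner". Coordinates are stored in double
precision.

## The ICP registration model

`icp(P, Q)` fits the rigid transform aligning the moving cloud $P$ (the
follow-up femur) onto the fixed reference $Q$ (the postoperative femur) by
iterating:

1. **Initialisation.** The centroid-matching translation
   $t_0 = \bar q - \bar p$. No rotational pre-alignment is attempted: the
   method assumes both models were reconstructed with the same initial
   orientation (shaft roughly along $z$), so the residual rotational offset
   is small. Empirically the fit converges to machine precision from
   offsets up to about 20° / 20 mm on the phantom geometry (this is a
   tested property); beyond that, point-to-point ICP can fall into a local
   minimum, as any ICP does without global initialisation.
2. **Correspondence.** Each point of $P$ is paired with its nearest
   neighbour in $Q$, found with a kd-tree built once per fit ( $Q$ is
   static). Distance ties are broken toward the lowest reference index so
   results are bit-reproducible.
3. **Rejection.** Wrong correspondences — from partial overlap and from
   segmentation artifacts — are vetoed two ways when `use_rejection` is on:
   * *Direction-vector threshold.* Each point carries a local outward
     direction: the unit vector from the centroid of its $k = 10$ nearest
     neighbours (within its own cloud) to the point. On interior-filled
     ("solid") clouds, the kind the reconstruction pipeline produces, this
     points outward from the local mass. A pair whose two directions
     disagree by more than `rejection_angle_deg` (default 60°) is
     discarded; points whose direction is degenerate (locally symmetric
     neighbourhoods) abstain rather than veto. The moving cloud's
     directions are computed once and rotated with the accumulated
     transform — neighbourhoods are rigid-invariant, so this is exact.
   * *Adaptive distance gate.* Pairs farther apart than 3× the median pair
     distance are discarded. This is the standard trimming device against
     gross outliers (reconstruction artifacts that have no true
     counterpart); an optional hard cap `max_pair_distance_mm` is also
     available but off by default.
   The precise rejection rule is a design choice: a "direction vector
   threshold" admits several readings (surface normals, displacement
   directions, neighbourhood directions), and the neighbourhood-centroid
   form was chosen because it needs no normal estimation and behaves well
   on filled clouds.
4. **Update.** The rigid transform minimising the mean squared pair
   distance $E(R,t) = \frac1n \sum_i \lVert q_i - (Rp_i + t) \rVert^2$ has
   the closed-form Kabsch solution: SVD of the cross-covariance of the
   centred pairs, with the determinant-corrected reflection fix. Fewer
   than 3 pairs, or a collinear pair configuration (second singular value
   below $10^{-9}$ of the first), is a degenerate-geometry error. Each
   update composes onto the accumulated total transform, which is
   re-orthonormalised at every composition so round-off cannot drift the
   rotation off the manifold.
5. **Convergence.** Iteration stops when the relative change in $E$ falls
   below `cost_tolerance` (default $10^{-6}$) or at `max_iterations`
   (default 125, the plateau point for this registration task — the tested
   plateau property shows the sub-0.5 mm fraction changes by less than 0.1
   percentage points between 125 and 250 forced iterations). Setting
   `cost_tolerance = 0` forces the full iteration count, which is how the
   plateau is probed.

$E$ is reported over *accepted* pairs (the cost divides by the number of
correspondences actually used); whether the original formulation averaged
over all points or accepted pairs is not specified, and this reading is
the self-consistent one for a trimmed estimator. The classic monotonicity
guarantee of point-to-point ICP (non-increasing $E$) holds when rejection
is disabled — with trimming, the accepted set changes between iterations
and monotonicity is no longer guaranteed in theory; the suite asserts it
for the untrimmed case only.

## Registration quality

`registration_quality(transformed, reference)` reports the mean and
maximum nearest-neighbour distance and the fraction of points *strictly*
below each threshold (defaults 0.5 mm — "coincident points" — and 2 mm).
Strict inequality is a deliberate reading of "less than"; boundary points
do not count. The measure is asymmetric by construction (registered cloud
→ reference), matching how alignment is evaluated in this workflow, and is
invariant to a common rigid motion of both clouds.

## Pin measurement

* **Axis.** The first principal component of the pin cloud (eigenvector of
  the centred covariance with the largest eigenvalue). If the top two
  eigenvalues coincide within $10^{-9}$ the axis is ambiguous and an error
  is raised. PCA axes are sign-ambiguous, so "top" is fixed by a rough
  user hint (`top_hint`, default $+z$); within the pipeline, the follow-up
  pin inherits the postoperative pin's axis as its hint, which guarantees
  consistent endpoint pairing.
* **Endpoints.** Points are projected onto the axis; the extent is
  $\max - \min$ projection. Each endpoint lies *on the fitted axis* at the
  axial position of the cap-slab mean: the mean projection of points
  within a 2 mm slab at the extreme, pushed out by half the slab width.
  For a uniformly sampled cylinder the pushed-out slab mean sits exactly
  at the physical end face. This is the "oriented-bounding-box face
  centre" reading of endpoint extraction — extreme single points are too
  noise-sensitive, and raw slab centroids sit half a slab short of the
  face and off-axis by sampling noise. The slab width is configurable.
* **Scale calibration.** CT-derived models can carry a small global scale
  error; the known physical pin length calibrates it. The calibration
  factor is `nominal / extent` using the *axial extent*, because the
  extent is exactly scale-equivariant (PCA directions are scale-invariant,
  projections scale linearly), which makes calibration idempotent to
  machine precision: calibrating an already-calibrated cloud changes the
  scale by $<10^{-9}$. The slab-based endpoint distance differs from the
  extent only by sampling noise, but is not exactly equivariant (the slab
  width is physical), so it is not used for calibration. Within a case,
  each epoch is scaled by the mean of its two pins' factors.
* **Hook direction and the pin frame.** The pin-local frame has $z$ along
  the axis (toward the top), $y$ along the hook direction orthogonalised
  against $z$ (positive toward hook elongation), and $x = y \times z$ —
  an orthonormal right-handed triad. The hook direction can be supplied
  as a rough hint (it is projected perpendicular to the axis; a hint
  within 1° of the axis is a degenerate-frame error) or estimated from
  the cloud as the mean off-axis offset of the outer half of the top
  third of the pin — the deployed hook is the dominant mass asymmetry
  there. The estimate assumes an interior-filled cloud; on hollow surface
  clouds the outer-half selection is uninformative and a hint should be
  given. The auto-estimate is a rough (order-10°) but sign-correct
  direction; since it only orients the $x$/$y$ split of the transverse
  plane, a supplied hint is preferred when transverse components matter.
* **Migration measures.** The relative angle between the two epochs' axes
  is $\arccos |a \cdot b| \in [0°, 90°]$ — sign-invariant because PCA axes
  are unoriented. Endpoint movements are Euclidean distances between
  corresponding endpoints; anti-aligned axes (which would silently swap
  top and bottom) raise an error. Displacement vectors are decomposed in
  the *postoperative* pin's frame. Which epoch's frame to use was an open
  choice; the postoperative frame is the clinically natural reference
  ("where was the pin heading relative to where it was placed") and is
  applied to both endpoints' displacement vectors. Orthonormality makes
  the decomposition norm-preserving, so the components always recombine
  to the movement scalar (tested to $10^{-6}$).

## The landmark (traditional) baseline

The manual workflow is implemented for comparison: the medullary-canal
centerline (through two picked points) is the femoral $z$-axis, positive
toward the greater trochanter; the origin is the foot of the perpendicular
from the picked lesser-trochanter point A; $x$ points at A and
$y = z \times x$. Landmarks are *picked*, not detected — automating canal
detection is out of scope, and the centerline uses exactly two points
(canal cylinder fitting would be a future refinement). Endpoint
displacement is the Euclidean distance between picked coordinates, and
relative errors are reported against repeated manual reference
measurements. In comparison tables, displacements are rounded to two
decimals *before* the relative error is formed — the convention such
tables are reported with (all values at two decimals), and the one that
makes the printed displacement and the printed error mutually consistent.

## The synthetic phantom

Patient CT data of this kind cannot be redistributed, so validation runs
on a seeded synthetic stand-in, and every dataset carries its full ground
truth (scanner pose change, per-pin migration transform, analytic endpoint
displacements and their frame components).

What it emulates, and the defaults:

* a solid tube (length 120 mm, radius 15 mm, ~2000 points) with a solid
  hemispherical bump (radius 12 mm) near the top — the cropped
  partial-femur reference with its trochanteric prominence, which removes
  rotational symmetry; interiors are filled because the reconstruction
  pipeline fills models to reduce noise;
* two solid pins of 6.5 mm diameter (radius 3.25 mm) and nominal lengths
  80 and 90 mm — the typical implanted pair — inserted at 45°, each with
  a hook fin (4 mm protrusion, top third, 15% of pin points) breaking
  axial symmetry;
* a follow-up scanner pose change sampled at 3–10° about a random axis
  and ±10 mm translation — the scale of pose differences between scans
  reconstructed with the same initial orientation;
* per-pin migration parameterised as axial translation plus a tilt about
  the pin centre, the clinically observed motion pattern (pins slide
  along their own axis, with small rotations); the regression suite
  samples axial slides of 1–15 mm and tilts of 0.5–8°, spanning observed
  endpoint movements of roughly 1–21 mm and angles up to ~8–11°;
* 0.3 mm iid Gaussian noise on the follow-up clouds, and 5% outlier
  points appended to the follow-up femur, sampled 2–20 mm off the
  surface — emulating threshold-segmentation artifacts. The postoperative
  reference is generated clean, reflecting the practice of manually
  cleaning the reference before registration.

What it does **not** emulate: real cortical-surface geometry and its
reconstruction-dependent smoothness, slice-spacing anisotropy (real scans
have 1.5–3 mm slice spacing, not isotropic noise), partial-overlap crops
that differ between epochs, metal artifacts near the pins, and any
deformation of the bone itself. Passing the phantom suite therefore
demonstrates the *algorithmic* correctness of registration, transfer and
measurement under noise and outliers — not the end-to-end accuracy on
clinical reconstructions, which additionally depends on segmentation
quality.

Reproducibility is strict: each dataset derives one RNG stream from its
seed (saving and restoring the session's RNG state), and the same spec is
bit-identical across calls.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use phantoms of ~2000 femur
points and 1200 points per pin, a 10-case regression suite, and forced
125/250-iteration runs for the plateau probe — sizes at which every
geometric estimate is comfortably stable while the whole suite runs in
seconds. Key tolerances: rigid-transform orthonormality $10^{-9}$;
ICP relative cost tolerance $10^{-6}$; degenerate-axis and collinearity
thresholds $10^{-9}$; duplicate-vertex dedup $10^{-6}$ mm on file import;
hook-degeneracy threshold 10% of the mean off-axis radius (a symmetric
cloud's mean offset is pure sampling noise, far below that). Nearest
neighbours are exact (no approximation), with deterministic tie-breaks.

## Known limitations

* Point-to-point ICP needs rough pre-orientation (~20°); there is no
  global registration fallback.
* The two clouds are assumed to represent the same anatomy at comparable
  density; strongly differing crops shrink the usable correspondence set,
  and the quality metrics should be inspected before trusting a report.
* Hook auto-estimation needs a filled, asymmetric pin cloud; supply
  hints otherwise.
* Landmark detection for the traditional baseline is manual by design.
* File import extracts mesh vertices (no surface resampling), which
  matches registration on reconstruction vertices but ties point density
  to the source meshing.
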