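# pinmigrate

Quantifying the postoperative migration of femoral-neck fixation pins from
3D point clouds.

## The problem

Femoral neck fractures in the elderly are routinely stabilised with pairs of
fixation pins (e.g. the 6.5 mm Hansson pin with its deployable hook).
Whether the pins stay put during the months of recovery is clinically
important — implant migration compromises reduction and predicts
complications — but the two CT scans that would answer the question
(immediately postoperative, and at follow-up) are acquired with the patient
in different poses, on different scanners, so the reconstructed 3D models
live in different coordinate systems. The traditional answer is manual: a
surgeon picks anatomical landmarks in the CT viewer, builds a femoral
coordinate system by hand, and measures endpoint coordinates twice — slow
and strongly operator-dependent.

`pinmigrate` implements the point-cloud alternative. A partial femur
(cropped below the femoral head, which may move with the fracture) is a
rigid structure common to both scans; registering the follow-up femur cloud
onto the postoperative one recovers the change of scanner pose, and that
transform — applied to the follow-up pin clouds — puts both epochs of each
pin into one frame where migration can be measured directly.

## The method

1. **Fine registration (ICP).** Starting from the centroid-aligning
   translation `t0 = centroid(Q) − centroid(P)`, the algorithm alternates
   (a) nearest-neighbour correspondence search of the moving cloud *P* in
   the fixed reference *Q* (kd-tree, deterministic tie-breaking), with
   rejection of implausible pairs — local outward directions disagreeing by
   more than 60° or distances beyond 3× the median — and (b) the
   closed-form least-squares rigid update (SVD of the cross-covariance,
   determinant-corrected so no reflection is returned), minimising
   `E(R,t) = (1/n) Σᵢ ‖qᵢ − (R·pᵢ + t)‖²`.
   Updates accumulate into one total rigid transform; iteration stops when
   the relative change in `E` drops below 1e-6 or at 125 iterations (the
   point beyond which registration accuracy plateaus).
2. **Quality metrics.** Mean and maximum nearest-neighbour distance of the
   registered cloud to the reference, and the fractions of points closer
   than 0.5 mm ("coincident") and 2 mm.
3. **Pin characterisation.** Each pin's central axis is the first principal
   component of its cloud; endpoints come from the oriented bounding box
   along that axis (cap-slab face centres, robust to noise spikes); the
   known physical pin length calibrates the global scale.
4. **Migration measures.** Per pin: the relative angle
   `acos(|a·b|) ∈ [0°, 90°]` between the two epochs' axes; Euclidean
   movement `d = √((x₁−x₂)² + (y₁−y₂)² + (z₁−z₂)²)` of the top and bottom
   endpoints; and the displacement vectors decomposed in the postoperative
   pin-local frame (z = pin axis toward the top, y = hook direction, x =
   y × z), which separates axial sliding from transverse drift.
5. **Traditional baseline.** The landmark workflow is also implemented:
   a femoral frame from the medullary-canal centerline and the lesser
   trochanter, endpoint displacement from picked coordinates, and relative
   errors against repeated manual reference measurements.

Patient CT data of this kind are not publicly distributable, so the package
ships a seeded synthetic phantom generator — a solid partial-femur tube
with a trochanteric bump, two solid pins with a hook fin, known ground-truth
pose change, per-pin migration, surface noise and segmentation-artifact
outliers — against which every stage is validated.

## Worked example

```r
library(pinmigrate)

ph  <- generate_phantom(phantom_spec(seed = 42))   # synthetic case
fit <- icp(ph$followup$femur_ref, ph$postop$femur_ref)
fit
#> ICP rigid registration
#>   2100 points matched onto 2000 reference points
#>   iterations: 8 (converged)
#>   final cost E: 0.268428 mm^2 over 1782 accepted pairs (318 rejected)
#> Rigid transform (x -> R x + t)
#>   rotation angle: 5.0122 deg
#>   translation:    (1.0430, -9.1000, 2.0313) mm
```

The fit recovers the phantom's true pose change (4.99°). The full pipeline
then measures the pins:

```r
rep <- pin_migration(ph$postop, ph$followup,
                     hook_hints = lapply(ph$truth$pins, `[[`, "hook_direction"))
rep
#> Pin migration report — case
#>   femur registration: 7 iterations, final E 0.3645 mm^2
#>   quality: mean 0.72 mm, max 14.59 mm, <0.5 mm 41.67%, <2 mm 96.48%
#>
#> Relative angle and endpoint movement:
#>       pin relative_angle_deg top_movement_mm bottom_movement_mm
#>  proximal               2.50            5.58               5.42
#>    distal               1.98            4.53               4.16
#>
#> Displacement components in the postoperative pin frame (mm):
#>       pin endpoint  x_mm  y_mm  z_mm
#>  proximal      top  0.57  1.56 -5.32
#>  proximal   bottom -0.70 -1.67 -5.11
#>    distal      top -1.38  0.57 -4.27
#>    distal   bottom  1.49 -0.60 -3.84
```

The phantom was built with a −5 mm axial slide plus 2.5° tilt of the
proximal pin and −4 mm plus 2° of the distal pin (true top movements 5.33
and 4.32 mm): the report recovers the angles to ≈0.03°, the movements to
a few tenths of a millimetre, and the z-components show the axial slide
with the transverse components near the noise floor. The maximum quality
distance (14.6 mm) is driven by the injected segmentation-artifact
outliers, which the correspondence rejection keeps out of the fit.

A command-line wrapper over the same functions is at
`inst/cli/pinmigrate.R` (subcommands `simulate`, `register`, `measure`,
`evaluate`, `traditional`).

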