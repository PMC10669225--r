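---
title: "Modeling personalized virtual dental articulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling personalized virtual dental articulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(artikin)
```

## The problem

Occlusal analysis needs the relative rigid motion of the mandible against
the maxilla. Mechanical articulators approximate that motion with a fixed
joint mechanism (a Bennett-angle joint and a condylar-inclination joint)
and require a facebow to transfer the cast into the instrument's hinge-axis
frame. `artikin` models the same mechanism virtually: anatomy fixes the
reference frame, tracked jaw motion personalizes the joint constraints, and
the mandibular pose is solved numerically for any incisal-edge target.

This vignette records the model, its assumptions, the numerical choices,
and what the synthetic test bed does and does not demonstrate.

## Coordinate conventions

All lengths are millimetres and angles radians internally (degrees at the
user surface for the two clinical angles). The articulator frame is:

* origin at the midpoint of the intercondylar axis;
* +X toward the patient's right condyle (the hinge axis);
* +Z superior, normal to the chosen reference plane (Frankfurt through the
  infraorbital point, Camper through the nasal alar point);
* +Y = Z × X, anterior; right-handed.

With this choice the rest condyles sit at (±w/2, 0, 0) for intercondylar
width w, the sagittal plane is x = 0 and the horizontal plane z = 0, so the
planar projections used in path fitting are literal coordinate drops. The
anatomical sources never pin an axis convention; this one was chosen so
that sagittal and horizontal projections are coordinate planes, and it is
applied consistently everywhere (a different convention would only
conjugate every transform by a fixed rotation).

`build_articulator_frame()` orients the plane normal so that the anterior
landmark gets positive y; an `up_hint` vector (default CT +z) is only
checked against, emitting a diagnostic when it disagrees — a disagreement
almost always means swapped left/right condyle labels.

## The forward model

The joint chain is expressed with homogeneous transforms carrying frame
tags. `articulator_joint_chain()` builds

* `T01 = translation(p01) · Rot_x(θ_sag) · Rot_z(θ1)` (world → Bennett
  joint) and
* `T12 = translation(p12) · Rot_x(θ2)` (Bennett joint → inclination joint),

with the left chain the sagittal mirror of the right. A mandibular pose is
six numbers (θx, θy, θz, tx, ty, tz) about the working-side condyle c:

    q = c + R (p − c) + t,   R = Rz(θz) · Ry(θy) · Rx(θx).

The rotation order is fixed; no other Euler convention is exposed.

## Personalized condylar path

From tracked condyle trajectories the path model keeps three coupled
representations per side:

* **sagittal quadratic** z = a·y² + b·y + c fitted by ordinary least
  squares to the protrusion track's (y, z) projection. The *condylar
  inclination* is atan|dz/dy| evaluated at the rest point (the first,
  centric-occlusion sample), reported in degrees against the reference
  plane;
* **horizontal line** x = m·y + k fitted to the same-side lateral-excursion
  track's (x, y) projection; the *Bennett angle* is atan|m|;
* a **clamped cubic NURBS** curve through the 3D protrusion samples
  (chord-length parameterization, uniform weights by default, least-squares
  control points, `max(4, ⌈N/5⌉)` control points capped at 25 — the curve
  is retained for export and visualization; the scalar constraint functions
  come from the planar fits so the inverse problem stays one-dimensional in
  y). Non-uniform weights are supported by the evaluator; nothing in
  practice requires them, so uniform is the default.

Outside the fitted y-domain both planar curves continue linearly from the
nearest endpoint and an `artikin_extrapolation` warning is signalled:
recordings stop at the extreme position, and a solver probing slightly
beyond the data should be told so rather than silently polynomial-
extrapolated.

## Inverse kinematics

For a measured incisal target the six constraints are: the posed incisal
point matches the target (3); the working condyle stays on its path,
tx = f(y₀+ty) − x₀ and tz = g(y₀+ty) − z₀ (2); and θy equals the roll of
the intercondylar line measured from the posed condyles,
atan2(z_L′−z_R′, x_L′−x_R′) wrapped into (−π/2, π/2] so the value is
independent of condyle labeling (1). The wrap also makes the residual
well-posed: with rotations taken about the working condyle, the unique
root keeps the pose's θy consistent with the geometry it produces.

`solve_pose()` runs Newton–Raphson with a central finite-difference
Jacobian (step 10⁻⁶ per component — the residuals are smooth at the mm
scale, and an analytic Jacobian buys nothing at desk-scale problem sizes),
step-halving damping when a full step fails to reduce the residual norm,
and a component-wise convergence test max|r| < 10⁻⁸ applied to mm and rad
alike — the mixed-unit tolerance avoids an arbitrary weighting between
translation and rotation errors. The cap is 100 iterations; in practice
warm-started solves converge in 2–4. `trajectory_ik()` warm-starts each
sample from the previous solution, cold-starting after a failure and
marking failed samples as gaps rather than aborting.

For symmetric motions (protrusion, opening) the working side must still be
named; the package's convention, used throughout its own simulations, is
the right side. Paths are fitted per side, each from the lateral excursion
toward that side.

## Trajectory agreement

`average_trajectory_error()` is the mean Euclidean distance between
index-aligned samples — the mean, not the mean of squares, which is what
keeps the number in mm; a squared variant sits behind a flag. ATE errors
out on length mismatch instead of resampling. The discrete Fréchet
distance uses the iterative Eiter–Mannila dynamic program (O(N·M) memory,
no recursion limits) and handles unequal lengths natively.
`compare_movement()` assembles the movement × condyle × direction ×
repetition table, per-direction means and the grand mean over all
individual cells, mirroring the verification protocol in which each
movement runs from centric occlusion to the extreme position and back
twice.

`split_repetitions()` segments a recording at local extrema of
distance-from-rest (window max(3, N/10) samples, peaks above half the
maximum excursion); with the synthetic generator's known cycle structure,
`movement_segments()` gives the exact protocol indices instead.

## Occlusion playback

Tooth surfaces become sphere proxies on a voxel-downsampled vertex grid
(defaults: 0.5 mm spacing, 0.3 mm radius — small enough to resolve
cusp-scale contacts on desk-scale meshes; both configurable). Collision
candidates come from spatial hashing with cell size twice the largest
radius, which provably returns the identical pair set to the all-pairs
scan (and is tested against it). Interference beyond a 0.01 mm clearance
is resolved by bisecting an added inferior translation of the pose — a
hinge-opening proxy — up to a 1 mm budget; past that an
`unresolvable-interference` error carries the contact report. A
constrained re-solve about the hinge axis would be the physically richer
alternative; pure −Z translation was chosen as the minimal, predictable
adjustment and is flagged on the returned pose. Contacts are always
reported, even when resolved.

## The synthetic patient

`generate_patient()` draws geometry from ranges that follow textbook
articulator norms: intercondylar width 100–120 mm, Bennett angle 5–20°,
condylar inclination 25–50°, condyle radius 8–12 mm, incisal point near
(0, 90–105, −35…−45) mm. The true condylar path is the quadratic + line
model itself with a small personalized curvature (|a| ≤ 0.015 mm⁻¹), so
path-fitting recovery is exactly identifiable. Movements advance the
working condyle along the true path with a smooth cosine ramp (protrusion
over the full fitted domain, lateral excursions with a ±4° yaw and a short
Bennett advance, opening with a 20° hinge rotation), derive the pose from
the same constraint system the solver uses, and add isotropic Gaussian
noise per emitted point.

The noise model is deliberately simple — independent, isotropic, identical
across markers. Real optical tracking has anisotropic, distance-dependent,
temporally correlated error and marker-rigidity violations; passing tests
at σ = 0.5 mm therefore shows the pipeline's robustness to magnitude, not
to structure, of real tracking error. Likewise the synthetic face (an
ellipsoid patch with a nose ridge) exercises ICP's geometry but not real
scan artifacts. The marker-stream synthesis inverts the tracking chain
exactly, so camera-wobble cancellation is a property of the chain, not of
the data.

Determinism: every sampler derives its stream from the patient seed and a
fixed per-stream tag, restores the caller's RNG state afterwards, and
keeps derived seeds below 2³¹.

## Problem sizes and tolerances in the shipped checks

The test suite and the acceptance script run the full chain at sizes a
workstation handles in seconds per case: 12–50 samples per half-cycle, two
cycles, 150–500-point registration clouds, 20–100 seeds per Monte-Carlo
sweep. Key figures the suite itself computes: noise-free FK/IK closure
below 10⁻⁵ mm Fréchet; Bennett and inclination medians within 0.5° at
σ = 0.1 mm; ICP rotation medians within 0.5° at σ = 0.2 mm; grand-mean
Fréchet within [0.5, 3] mm at σ = 0.5 mm.

## Known limitations

* Kinematics only: no muscle forces, no contact mechanics, no
  immediate-side-shift or Fischer-angle modeling beyond what the planar
  fits capture.
* Pose streams use nearest-sample lookup; rotation interpolation is out of
  scope.
* ICP is point-to-point with 10% trimming; point-to-plane variants are not
  provided.
* Mesh I/O covers STL (ASCII/binary) and ASCII PLY with 10⁻⁶ mm vertex
  welding; no DICOM or proprietary scanner formats.
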