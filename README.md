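# artikin — a personalized virtual dental articulator

Dental articulators reproduce the relative motion of the mandible against
the maxilla so that occlusion can be analyzed and restorations designed.
Mechanical articulators approximate this motion with fixed joints and
require a facebow transfer to relate the dental cast to the skull's hinge
axis. `artikin` implements the fully virtual alternative: the articulator
frame is derived from anatomical landmarks (a *virtual facebow*), the
condylar path is *personalized* from optically tracked jaw motion, and
mandibular kinematics are solved numerically — no physical instrument
involved.

The package is aimed at researchers in craniofacial biomechanics and
digital dentistry who need a scriptable, testable articulation model.

## The model

**Frames.** The articulator (world) frame has its origin at the midpoint of
the intercondylar axis, +X toward the right condyle (the hinge axis),
+Z superior (normal to the Frankfurt or Camper reference plane), +Y
anterior. `build_articulator_frame()` constructs the rigid transform from
CT-frame landmarks; condyle centers come from least-squares sphere fits
(`fit_sphere()`), and face-scan clouds register to CT skin via Kabsch/ICP
(`kabsch_align()`, `icp_register()`).

**Motion tracking.** A dual-marker optical stream (camera←upper-marker,
camera←lower-marker transforms per frame) is reduced through the chain

    p_articulator = T_0up · T_camup⁻¹ · T_camlow · p_low

so arbitrary camera motion cancels (`track_landmark_trajectory()`).

**Personalized condylar path.** Tracked condyle trajectories are projected
onto the sagittal plane (quadratic fit `z = a y² + b y + c`, carrying the
condylar inclination `atan|dz/dy|` at rest) and the horizontal plane (line
`x = m y + k`, carrying the Bennett angle `atan|m|`), and combined into a
clamped cubic NURBS space curve

    C(u) = Σⱼ N_{j,p}(u) wⱼ Pⱼ / Σⱼ N_{j,p}(u) wⱼ .

**Inverse kinematics.** The 6-DOF mandibular pose
(θx, θy, θz, tx, ty, tz), taken about the working-side condyle with
rotation order Rz·Ry·Rx, is solved per incisal-edge sample by
Newton–Raphson on six constraints: three match the posed incisal point to
its measured position, two hold the working condyle on its personalized
path (tx = f(y₀+ty) − x₀, tz = g(y₀+ty) − z₀), and one ties θy to the roll
of the intercondylar line, atan2(z_L′−z_R′, x_L′−x_R′).

**Verification.** Simulated condylar trajectories (IK from the incisal
recording) are compared with tracked ones using the average trajectory
error, ATE = (1/N) Σ‖pᵢ − f⁻¹(qᵢ)‖, and the discrete Fréchet distance
(Eiter–Mannila dynamic program), aggregated per movement × condyle ×
direction × repetition (`compare_movement()`).

**Occlusion playback.** `playback()` drives the mandible along an incisal
guidance path, detecting tooth interference with sphere proxies
(`mesh_to_sphere_proxies()`, `detect_collisions()`) and resolving it by
bisecting an opening translation (`adjust_motion_path()`).

A seeded synthetic-patient generator (`generate_patient()`,
`simulate_movement()`, `emit_marker_stream()`) emulates the CT and
tracking inputs with known ground truth, so the whole pipeline is testable
without a scanner or camera.

## Worked example

Simulate a patient tracked with 0.5 mm noise (a low-accuracy laboratory
regime), personalize the condylar paths, run inverse kinematics on the
incisal recording and compare simulated against tracked right-condyle
trajectories:

```r
library(artikin)
pat <- generate_patient(42, overrides = list(noise_sigma = 0.5))

prot  <- simulate_movement(pat, "protrusion",      n_samples = 12)
lat_r <- simulate_movement(pat, "right_excursion", n_samples = 12)
lat_l <- simulate_movement(pat, "left_excursion",  n_samples = 12)

path_r <- fit_condylar_path(prot$condyle_right, lat_r$condyle_right, "right")
path_l <- fit_condylar_path(prot$condyle_left,  lat_l$condyle_left,  "left")
ik <- trajectory_ik(prot$incisal, pat$landmarks, path_r, path_l, "right")

segs <- movement_segments(12, 2)
tracked <- list(); simulated <- list()
for (lab in names(segs)) {
  idx <- segs[[lab]]
  tracked[[paste0("protrusion/right_condyle/", lab)]] <-
    trajectory(seq_along(idx) / 30, prot$condyle_right$points[idx, ])
  simulated[[paste0("protrusion/right_condyle/", lab)]] <-
    trajectory(seq_along(idx) / 30, ik$condyle_right$points[idx, ])
}
compare_movement(tracked, simulated)
```

Output:

```
<trajectory_comparison>
    movement       condyle direction frechet_mm
1 protrusion right_condyle  backward   1.826651
2 protrusion right_condyle   forward   1.615857
grand mean: 1.72 mm over 4 cells
```

The ground-truth condylar inclination of this patient is 32.15°; the fit
recovers 32.56° despite the noise. The 1.7 mm grand-mean Fréchet distance
is dominated by the injected 0.5 mm tracking noise on both trajectories —
at `noise_sigma = 0` the same pipeline closes to below 10⁻⁵ mm.

## Command-line tool

`inst/cli/artikin` is a thin Rscript over the same functions:

```sh
artikin synth    --seed 7 --movement protrusion --sigma 0.1 --out-dir run/
artikin facebow  --landmarks ct_lm.json --plane camper --out frame.json
artikin register --src face_scan.ply --dst ct_skin.ply --out T.json
artikin fit-path --protrusion prot.csv --lateral lat.csv --side right --out path.json
artikin ik       --incisal traj.csv --landmarks lm.json --path-right pr.json \
                 --path-left pl.json --side right --out-dir out/
artikin compare  --tracked a.csv --simulated b.csv --labels protrusion/right_condyle/forward/rep1 \
                 --out report.csv
```

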