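#' Generate a ground-truth virtual patient
#'
#' Draws an anatomically plausible articulator geometry from a seeded
#' generator: intercondylar width 100-120 mm, Bennett angle 5-20 degrees,
#' condylar inclination 25-50 degrees, condyle radius 8-12 mm, incisal
#' point near (0, 90-105, -(35-45)) mm, with the condyles at rest on the
#' reference plane at (+/- width/2, 0, 0). The true condylar paths are a
#' sagittal quadratic through the rest condyle (slope -tan(inclination) at
#' rest, with a small personalized curvature) and a horizontal Bennett line
#' (slope +/- tan(bennett)). Every downstream synthetic stream derives its
#' randomness from the patient's seed, so regeneration is reproducible.
#'
#' @param seed integer seed.
#' @param overrides named list pinning any of `width`, `bennett_deg`,
#'   `inclination_deg`, `condyle_radius`, `incisal_point`, `anterior_point`,
#'   `curvature`, `y_max`, `noise_sigma`.
#' @return A `virtual_patient`: list with `landmarks`, `params`,
#'   `true_paths` (per side), `condyle_radius`, `noise_sigma`, `seed`.
#' @export
generate_patient <- function(seed, overrides = list()) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  draw <- function(name, lo, hi) {
    if (!is.null(overrides[[name]])) overrides[[name]] else stats::runif(1, lo, hi)
  }
  width <- draw("width", 100, 120)
  bennett <- draw("bennett_deg", 5, 20)
  incl <- draw("inclination_deg", 25, 50)
  cradius <- draw("condyle_radius", 8, 12)
  curv <- draw("curvature", -0.015, 0.015)
  y_max <- draw("y_max", 7, 9)
  incisal <- if (!is.null(overrides$incisal_point)) overrides$incisal_point
             else c(0, stats::runif(1, 90, 105), -stats::runif(1, 35, 45))
  anterior <- if (!is.null(overrides$anterior_point)) overrides$anterior_point
              else c(stats::runif(1, -2, 2), stats::runif(1, 70, 85), 0)
  noise_sigma <- if (!is.null(overrides$noise_sigma)) overrides$noise_sigma else 0

  lm <- anatomical_landmarks(condyle_right = c(width / 2, 0, 0),
                             condyle_left = c(-width / 2, 0, 0),
                             anterior_point = anterior,
                             incisal_point = incisal,
                             anterior_point_kind = "infraorbital",
                             frame = "articulator")
  b <- bennett * pi / 180; g <- incl * pi / 180
  params <- articulator_parameters(theta_sag = g, theta1 = b, theta2 = g,
                                   p01 = c(width / 2, 0, 0),
                                   intercondylar_width = width)
  # z = curv*y^2 - tan(incl)*y, x = +/- (tan(bennett)*y) +/- width/2
  paths <- list(
    right = condylar_path_from_coeffs(
      "right", sagittal = c(curv, -tan(g), 0),
      horizontal = c(tan(b), width / 2), y_domain = c(0, y_max), rest_y = 0),
    left = condylar_path_from_coeffs(
      "left", sagittal = c(curv, -tan(g), 0),
      horizontal = c(-tan(b), -width / 2), y_domain = c(0, y_max), rest_y = 0))
  structure(list(landmarks = lm, params = params, true_paths = paths,
                 condyle_radius = cradius, noise_sigma = noise_sigma,
                 seed = as.integer(seed),
                 bennett_deg = bennett, inclination_deg = incl),
            class = "virtual_patient")
}

# movement-specific deterministic sub-seed, kept well below 2^31
movement_seed <- function(patient, tag) {
  tags <- c(protrusion = 1L, right_excursion = 2L, left_excursion = 3L,
            opening = 4L, stream = 5L, condyle = 6L, skin = 7L)
  (patient$seed * 97L + tags[[tag]] * 131L) %% 2000000011L
}

# Pose consistent with the condylar-path and roll constraints at advance ty.
# theta_y is resolved by fixed-point iteration on the roll measured from the
# posed condyles, so generated poses satisfy the full 6-constraint system.
consistent_pose <- function(patient, side, ty, theta_x = 0, theta_z = 0) {
  lm <- patient$landmarks
  cw <- if (side == "right") lm$condyle_right else lm$condyle_left
  path <- patient$true_paths[[side]]
  pw <- evaluate_path(path, cw[2] + ty, warn = FALSE)
  tx <- pw$x - cw[1]; tz <- pw$z - cw[3]
  th_y <- 0
  for (k in 1:50) {
    v <- c(theta_x, th_y, theta_z, tx, ty, tz)
    R <- pose_rot(v)
    tr <- v[4:6] + cw - drop(R %*% cw)
    cr <- drop(R %*% lm$condyle_right + tr)
    cl <- drop(R %*% lm$condyle_left + tr)
    new <- condyle_height_rotation(cr, cl)
    if (abs(new - th_y) < 1e-15) { th_y <- new; break }
    th_y <- new
  }
  jaw_pose(theta_x, th_y, theta_z, tx, ty, tz, reference_side = side)
}

movement_profile <- function(movement) {
  switch(movement,
         protrusion = list(side = "right", ty_max = 1, theta_x = 0,
                           theta_z = 0),
         opening = list(side = "right", ty_max = 0.75, theta_x = -20 * pi / 180,
                        theta_z = 0),
         right_excursion = list(side = "right", ty_max = 0.25, theta_x = 0,
                                theta_z = -4 * pi / 180),
         left_excursion = list(side = "left", ty_max = 0.25, theta_x = 0,
                               theta_z = 4 * pi / 180),
         stop("invalid-argument: unknown movement"))
}

#' Simulate a border movement of a virtual patient
#'
#' Advances the working-side condyle along the true condylar path from the
#' centric-occlusion position to the extreme position and back
#' (`cycles` times), derives the mandibular pose per sample from the
#' forward model (path constraints plus roll consistency), maps the incisal
#' point and both condyles into the articulator frame, and finally adds
#' seeded isotropic Gaussian noise to every emitted point.
#'
#' @param patient a `virtual_patient`.
#' @param movement one of `"protrusion"`, `"right_excursion"`,
#'   `"left_excursion"`, `"opening"`.
#' @param n_samples samples per half-cycle (>= 4).
#' @param cycles out-and-back repetitions (default 2).
#' @param noise_sigma isotropic noise s.d. in mm (default the patient's).
#' @param fs sampling rate used for timestamps, Hz.
#' @return list with `incisal`, `condyle_right`, `condyle_left`
#'   (trajectories), `poses`, `working_side`, `movement` and the noise-free
#'   `clean` trajectories.
#' @export
simulate_movement <- function(patient, movement = c("protrusion",
                                                    "right_excursion",
                                                    "left_excursion",
                                                    "opening"),
                              n_samples = 20L, cycles = 2L,
                              noise_sigma = patient$noise_sigma, fs = 30) {
  movement <- match.arg(movement)
  if (n_samples < 4L)
    stop("invalid-argument: need >= 4 samples per half-cycle")
  prof <- movement_profile(movement)
  side <- prof$side
  y_max <- patient$true_paths[[side]]$y_domain[2]
  half_up <- seq(0, 1, length.out = n_samples)
  s <- half_up
  for (k in seq_len(cycles * 2L - 1L)) {
    nxt <- if (k %% 2L == 1L) rev(half_up) else half_up
    s <- c(s, nxt[-1])
  }
  # smooth the ramp so velocities vanish at the turning points
  s <- (1 - cos(pi * s)) / 2
  lm <- patient$landmarks
  cw <- if (side == "right") lm$condyle_right else lm$condyle_left
  poses <- lapply(s, function(si)
    consistent_pose(patient, side, ty = si * prof$ty_max * y_max,
                    theta_x = si * prof$theta_x, theta_z = si * prof$theta_z))
  pts <- function(p) t(vapply(poses, function(ps) apply_jaw_pose(ps, cw, p),
                              numeric(3)))
  t_s <- (seq_along(s) - 1L) / fs
  clean <- list(incisal = pts(lm$incisal_point),
                condyle_right = pts(lm$condyle_right),
                condyle_left = pts(lm$condyle_left))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(movement_seed(patient, movement))
  noisy <- lapply(clean, function(M)
    M + matrix(stats::rnorm(length(M), 0, noise_sigma), nrow(M), 3))
  mk <- function(M, what)
    trajectory(t_s, M, "articulator", sprintf("%s/%s", movement, what))
  list(incisal = mk(noisy$incisal, "incisal"),
       condyle_right = mk(noisy$condyle_right, "right_condyle"),
       condyle_left = mk(noisy$condyle_left, "left_condyle"),
       clean = list(incisal = mk(clean$incisal, "incisal"),
                    condyle_right = mk(clean$condyle_right, "right_condyle"),
                    condyle_left = mk(clean$condyle_left, "left_condyle")),
       poses = poses, working_side = side, movement = movement)
}

#' Protocol segment indices of a simulated movement
#'
#' A simulated recording runs rest -> extreme -> rest for `cycles`
#' repetitions with `n_samples` per half-cycle (shared turning samples).
#' Returns the index ranges and `forward/repN` / `backward/repN` labels of
#' each half-cycle, for building verification-table cells.
#'
#' @param n_samples samples per half-cycle.
#' @param cycles out-and-back repetitions.
#' @return named list of integer index vectors.
#' @export
movement_segments <- function(n_samples, cycles = 2L) {
  out <- list()
  for (k in seq_len(2L * cycles) - 1L) {
    idx <- (1L + k * (n_samples - 1L)):(1L + (k + 1L) * (n_samples - 1L))
    lab <- sprintf("%s/rep%d", if (k %% 2L == 0L) "forward" else "backward",
                   k %/% 2L + 1L)
    out[[lab]] <- idx
  }
  out
}

#' Synthesize a dual-marker optical tracking stream
#'
#' Builds upper-marker (static with respect to the articulator) and
#' lower-marker (rigid with the mandible) poses in a possibly moving camera
#' frame such that the tracking chain
#' `T_0_up * inv(T_cam_up) * T_cam_low` reproduces the movement's rigid
#' mandibular motion exactly. With `camera_wobble = "random_walk"` the
#' camera drifts by a seeded random walk, which must cancel out of any
#' tracked trajectory.
#'
#' @param patient a `virtual_patient`.
#' @param movement result of [simulate_movement()].
#' @param camera_wobble `"none"` or `"random_walk"`.
#' @return list with `stream` (a `marker_pose_stream`), `T_0_up`,
#'   `marker_points` (rest landmarks expressed in the lower-marker frame)
#'   and `T_art_low_rest`.
#' @export
emit_marker_stream <- function(patient, movement,
                               camera_wobble = c("none", "random_walk")) {
  camera_wobble <- match.arg(camera_wobble)
  lm <- patient$landmarks
  side <- movement$working_side
  cw <- if (side == "right") lm$condyle_right else lm$condyle_left
  poses <- movement$poses
  n <- length(poses)
  # fixed marker mountings (arbitrary rigid offsets, frames tagged)
  T_0_up <- compose(make_translation(c(2, 85, 25)), make_rotation("x", 0.15))
  T_0_up$from <- "marker_up"; T_0_up$to <- "articulator"
  L0 <- compose(make_translation(c(-1, 95, -55)), make_rotation("y", -0.1))
  L0$from <- "marker_low"; L0$to <- "articulator"
  pose_T <- function(ps) {
    v <- pose_vector(ps)
    m <- diag(4)
    m[1:3, 1:3] <- pose_rot(v)
    m[1:3, 4] <- v[4:6] + cw - drop(m[1:3, 1:3] %*% cw)
    framed_transform(m, from = "articulator", to = "articulator",
                     validate = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(movement_seed(patient, "stream"))
  cam <- identity_transform()
  cam$from <- "articulator"; cam$to <- "camera"
  cam_up <- vector("list", n); cam_low <- vector("list", n)
  for (i in seq_len(n)) {
    if (camera_wobble == "random_walk") {
      dR <- compose(compose(make_rotation("x", stats::rnorm(1, 0, 0.01)),
                            make_rotation("y", stats::rnorm(1, 0, 0.01))),
                    make_rotation("z", stats::rnorm(1, 0, 0.01)))
      dT <- make_translation(stats::rnorm(3, 0, 0.5))
      step <- compose(dT, dR)
      step$from <- "camera"; step$to <- "camera"
      cam <- compose(step, cam)
    }
    M_i <- pose_T(poses[[i]])
    T_art_low_i <- compose(M_i, L0)
    up <- compose(cam, T_0_up)      # marker_up -> camera
    lo <- compose(cam, T_art_low_i) # marker_low -> camera
    cam_up[[i]] <- up; cam_low[[i]] <- lo
  }
  t_s <- movement$incisal$t
  inv_L0 <- invert(L0)
  list(stream = marker_pose_stream(t_s, cam_up, cam_low),
       T_0_up = T_0_up,
       marker_points = list(
         incisal = apply_transform(inv_L0, lm$incisal_point),
         condyle_right = apply_transform(inv_L0, lm$condyle_right),
         condyle_left = apply_transform(inv_L0, lm$condyle_left)),
       T_art_low_rest = L0)
}

#' Sample points on a condyle's superior hemisphere
#'
#' Seeded uniform directions on the superior half of the condyle sphere
#' plus isotropic Gaussian noise; input for sphere-fit testing.
#'
#' @param patient a `virtual_patient`.
#' @param side `"right"` or `"left"`.
#' @param n_points number of samples (>= 4).
#' @param noise_sigma noise s.d., mm.
#' @export
sample_condyle_surface <- function(patient, side = c("right", "left"),
                                   n_points = 200L, noise_sigma = 0) {
  side <- match.arg(side)
  if (n_points < 4L) stop("invalid-argument: need >= 4 surface points")
  center <- if (side == "right") patient$landmarks$condyle_right
            else patient$landmarks$condyle_left
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(movement_seed(patient, "condyle") + match(side, c("right", "left")))
  u <- matrix(stats::rnorm(3 * n_points), n_points, 3)
  u <- u / sqrt(rowSums(u^2))
  u[, 3] <- abs(u[, 3])  # superior hemisphere
  pts <- sweep(u * patient$condyle_radius, 2L, center, "+")
  pts + matrix(stats::rnorm(3 * n_points, 0, noise_sigma), n_points, 3)
}

#' Sample a pair of face-like point clouds for registration testing
#'
#' One seeded cloud on a synthetic face-like surface (an ellipsoid patch
#' with a nose ridge) and a copy taken through a known rigid transform plus
#' noise; the pair exercises ICP exactly as a face scan against CT skin.
#'
#' @param patient a `virtual_patient`.
#' @param n_points points per cloud (>= 10).
#' @param true_transform `framed_transform` applied to the copy (default a
#'   seeded small rigid perturbation).
#' @param noise_sigma noise s.d. added to the transformed copy, mm.
#' @return list with `src`, `dst` (point matrices) and `true_transform`.
#' @export
sample_skin_clouds <- function(patient, n_points = 300L,
                               true_transform = NULL, noise_sigma = 0) {
  if (n_points < 10L) stop("invalid-argument: need >= 10 points")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(movement_seed(patient, "skin"))
  # anterior patch of an ellipsoid (the face), mm
  a <- 65; b <- 90; c <- 110
  th <- stats::runif(n_points, -0.9, 0.9)         # azimuth from the y axis
  ph <- stats::runif(n_points, -0.7, 0.9)         # elevation
  pts <- cbind(a * cos(ph) * sin(th),
               b * cos(ph) * cos(th),
               c * sin(ph))
  # nose ridge: midline bump pushing the surface anteriorly
  bump <- 12 * exp(-(pts[, 1] / 9)^2 - ((pts[, 3] + 20) / 14)^2)
  pts[, 2] <- pts[, 2] + bump
  if (is.null(true_transform)) {
    true_transform <- compose(
      make_translation(stats::rnorm(3, 0, 2)),
      compose(compose(make_rotation("x", stats::rnorm(1, 0, 0.04)),
                      make_rotation("y", stats::rnorm(1, 0, 0.04))),
              make_rotation("z", stats::rnorm(1, 0, 0.04))))
  }
  dst <- apply_transform(true_transform, pts) +
    matrix(stats::rnorm(3 * n_points, 0, noise_sigma), n_points, 3)
  list(src = pts, dst = dst, true_transform = true_transform)
}
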