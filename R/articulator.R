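#' Articulator joint-chain parameters
#'
#' Geometry of the virtual articulator's joint chain. The world (articulator)
#' frame has its origin at the midpoint of the intercondylar axis, +X toward
#' the patient's right condyle along the hinge axis, +Z superior (normal to
#' the chosen reference plane) and +Y anterior. Joint 1 carries the Bennett
#' angle, joint 2 the condylar inclination adjuster; `theta_sag` tilts the
#' condylar-inclination plane relative to the horizontal plane.
#'
#' Angles are radians internally; lengths mm. A single set of values
#' describes the right-side chain; the left side is its mirror across the
#' sagittal plane unless per-side values are supplied via `left`.
#'
#' @param theta_sag,theta1,theta2 chain angles in radians (each |angle| < pi/2).
#' @param p01 3-vector mm, offset world -> joint 1.
#' @param p12 3-vector mm, offset joint 1 -> joint 2.
#' @param intercondylar_width distance between condyle centers, mm (> 0).
#' @param left optional named list overriding any of the five chain fields
#'   for the left side (values given in the left side's own mirrored sense).
#' @export
articulator_parameters <- function(theta_sag = 0, theta1 = 0, theta2 = 0,
                                   p01 = c(0, 0, 0), p12 = c(0, 0, 0),
                                   intercondylar_width = 110,
                                   left = NULL) {
  right <- list(theta_sag = theta_sag, theta1 = theta1, theta2 = theta2,
                p01 = as.numeric(p01), p12 = as.numeric(p12))
  lft <- right
  if (!is.null(left)) lft[names(left)] <- left
  x <- structure(list(right = right, left = lft,
                      intercondylar_width = intercondylar_width),
                 class = "articulator_parameters")
  validate_articulator_parameters(x)
  x
}

#' @rdname articulator_parameters
#' @param x an `articulator_parameters` object.
#' @export
validate_articulator_parameters <- function(x) {
  if (!is.finite(x$intercondylar_width) || x$intercondylar_width <= 0)
    stop("invalid-argument: intercondylar_width must be > 0")
  for (side in c("right", "left")) {
    s <- x[[side]]
    ang <- c(s$theta_sag, s$theta1, s$theta2)
    if (any(!is.finite(ang)) || any(abs(ang) >= pi / 2))
      stop("invalid-argument: chain angles must be finite with |angle| < pi/2")
    if (any(!is.finite(c(s$p01, s$p12))))
      stop("invalid-argument: joint offsets must be finite")
  }
  invisible(x)
}

#' Anatomical landmark set
#'
#' The three facebow reference points (two condyle centers and one anterior
#' point, either the infraorbital point for the Frankfurt plane or the nasal
#' alar point for Camper's plane) plus the incisal point, the kinematic
#' end-effector of the articulator model.
#'
#' @param condyle_right,condyle_left,anterior_point,incisal_point 3-vectors mm.
#' @param anterior_point_kind `"infraorbital"` or `"nasal_alar"`.
#' @param frame frame name the landmarks are expressed in.
#' @export
anatomical_landmarks <- function(condyle_right, condyle_left, anterior_point,
                                 incisal_point,
                                 anterior_point_kind = c("infraorbital",
                                                         "nasal_alar"),
                                 frame = "articulator") {
  x <- structure(list(condyle_right = as.numeric(condyle_right),
                      condyle_left = as.numeric(condyle_left),
                      anterior_point = as.numeric(anterior_point),
                      incisal_point = as.numeric(incisal_point),
                      anterior_point_kind = match.arg(anterior_point_kind),
                      frame = frame),
                 class = "anatomical_landmarks")
  validate_anatomical_landmarks(x)
  x
}

#' @rdname anatomical_landmarks
#' @param x an `anatomical_landmarks` object.
#' @export
validate_anatomical_landmarks <- function(x) {
  pts <- rbind(x$condyle_right, x$condyle_left, x$anterior_point,
               x$incisal_point)
  if (any(!is.finite(pts)) || nrow(pts) != 4L || ncol(pts) != 3L)
    stop("invalid-argument: landmarks must be finite 3-vectors")
  if (sqrt(sum((x$condyle_right - x$condyle_left)^2)) <= 1)
    stop("degenerate-geometry: condyle centers closer than 1 mm")
  # triangle area spanned with the anterior point
  v1 <- x$condyle_left - x$condyle_right
  v2 <- x$anterior_point - x$condyle_right
  area <- 0.5 * sqrt(sum(cross3(v1, v2)^2))
  if (area <= 1)
    stop("degenerate-geometry: anterior point nearly collinear with condyles")
  invisible(x)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Forward articulator joint chain
#'
#' Builds the two joint transforms of the articulator mechanism:
#' `T01` (world -> Bennett-angle joint) as
#' `translation(p01) * Rot_x(theta_sag) * Rot_z(theta1)` and `T12`
#' (joint 1 -> condylar-inclination joint) as
#' `translation(p12) * Rot_x(theta2)`. The left chain is the mirror of the
#' right chain across the sagittal plane.
#'
#' @param params an `articulator_parameters` object.
#' @param side `"right"` or `"left"`.
#' @return list with elements `T01` and `T12`.
#' @export
articulator_joint_chain <- function(params, side = c("right", "left")) {
  side <- match.arg(side)
  validate_articulator_parameters(params)
  s <- params[[side]]
  T01 <- compose(compose(make_translation(s$p01),
                         make_rotation("x", s$theta_sag)),
                 make_rotation("z", s$theta1))
  T12 <- compose(make_translation(s$p12), make_rotation("x", s$theta2))
  if (side == "left") {
    T01 <- mirror_transform(T01)
    T12 <- mirror_transform(T12)
  }
  T01$from <- paste0("joint1_", side); T01$to <- "articulator"
  T12$from <- paste0("joint2_", side); T12$to <- paste0("joint1_", side)
  list(T01 = T01, T12 = T12)
}

#' Map a joint-2 point to the world frame
#'
#' Collects condylar-path points expressed in the condylar-inclination joint
#' frame into the articulator (world) frame: `p_world = (T01 * T12) * p`.
#'
#' @param p 3-vector mm in the joint-2 frame.
#' @param T01,T12 chain transforms from [articulator_joint_chain()].
#' @export
map_joint2_point_to_world <- function(p, T01, T12) {
  apply_transform(compose(T01, T12), p)
}

#' Translation from the world frame to a condyle reference frame
#'
#' Returns the transform T0R (or T0L) taking articulator coordinates into a
#' frame with origin at the chosen condyle center and axes parallel to the
#' world axes.
#'
#' @param landmarks an `anatomical_landmarks` object in the articulator frame.
#' @param side `"right"` or `"left"`.
#' @export
world_to_condyle_frame <- function(landmarks, side = c("right", "left")) {
  side <- match.arg(side)
  if (!identical(landmarks$frame, "articulator"))
    stop(sprintf("frame-mismatch: landmarks are in frame '%s', expected 'articulator'",
                 landmarks$frame))
  c0 <- if (side == "right") landmarks$condyle_right else landmarks$condyle_left
  T <- make_translation(-c0)
  T$from <- "articulator"; T$to <- paste0("condyle_", side)
  T
}

#' 6-DOF mandibular pose
#'
#' The unknown of the inverse-kinematics problem: three rotations (radians,
#' composed as Rz*Ry*Rx) and a translation (mm), all taken about a reference
#' (working-side) condyle.
#'
#' @param theta_x,theta_y,theta_z rotations in radians (|angle| < bound).
#' @param t_x,t_y,t_z translation in mm.
#' @param reference_side working side the pose is referred to.
#' @param angle_bound physiological bound on each rotation (radians).
#' @export
jaw_pose <- function(theta_x = 0, theta_y = 0, theta_z = 0,
                     t_x = 0, t_y = 0, t_z = 0,
                     reference_side = c("right", "left"),
                     angle_bound = pi / 2) {
  v <- c(theta_x, theta_y, theta_z, t_x, t_y, t_z)
  if (any(!is.finite(v)))
    stop("invalid-argument: pose components must be finite")
  if (any(abs(v[1:3]) > angle_bound))
    stop("invalid-argument: pose angles exceed the physiological bound")
  structure(list(theta_x = theta_x, theta_y = theta_y, theta_z = theta_z,
                 t_x = t_x, t_y = t_y, t_z = t_z,
                 reference_side = match.arg(reference_side)),
            class = "jaw_pose")
}

pose_vector <- function(pose) {
  c(pose$theta_x, pose$theta_y, pose$theta_z, pose$t_x, pose$t_y, pose$t_z)
}

vector_pose <- function(v, side = "right", angle_bound = pi / 2) {
  jaw_pose(v[1], v[2], v[3], v[4], v[5], v[6], reference_side = side,
           angle_bound = angle_bound)
}

# 3x3 rotation Rz*Ry*Rx and 3-translation of a pose; kept as raw numerics
# (this is the innermost loop of the IK solver).
pose_rot <- function(v) {
  rot3("z", v[3]) %*% rot3("y", v[2]) %*% rot3("x", v[1])
}

#' Apply a jaw pose to points
#'
#' Moves mandibular points by the rigid displacement
#' `inv(T0R) * TRR' * T0R` where `TRR' = Trant * Rot_z * Rot_y * Rot_x` is
#' taken about the reference condyle: `q = c + R (p - c) + t`.
#'
#' @param pose a `jaw_pose`.
#' @param ref_condyle 3-vector mm, rest position of the reference condyle.
#' @param p a 3-vector or N x 3 matrix of points (mm, articulator frame).
#' @export
apply_jaw_pose <- function(pose, ref_condyle, p) {
  v <- pose_vector(pose)
  if (any(!is.finite(v))) stop("invalid-argument: non-finite pose")
  R <- pose_rot(v)
  tr <- v[4:6] + ref_condyle - drop(R %*% ref_condyle)
  if (is.null(dim(p))) drop(R %*% p + tr)
  else sweep(p %*% t(R), 2L, tr, "+")
}
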