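#' Sphere-proxy cloud for collision detection
#'
#' Tooth surfaces are approximated by small spheres centered on voxel-grid
#' downsampled mesh vertices; interference between the upper and lower arch
#' is then cheap sphere-sphere overlap.
#'
#' @param centers N x 3 matrix of sphere centers, mm.
#' @param radii per-sphere radii or one shared radius, mm (> 0).
#' @param source `"upper"` or `"lower"`.
#' @export
sphere_cloud <- function(centers, radii, source = c("upper", "lower")) {
  centers <- rbind(centers)
  if (!nrow(centers) || any(!is.finite(centers)))
    stop("invalid-argument: sphere centers must be finite and non-empty")
  radii <- rep_len(as.numeric(radii), nrow(centers))
  if (any(!is.finite(radii)) || any(radii <= 0))
    stop("invalid-argument: sphere radii must be > 0")
  structure(list(centers = centers, radii = radii,
                 source = match.arg(source)),
            class = "sphere_cloud")
}

#' Convert a triangle mesh to sphere proxies
#'
#' Downsamples mesh vertices on a voxel grid of the given spacing (keeping
#' the first vertex encountered in each occupied voxel, in vertex order)
#' and places one sphere of the given radius on each retained vertex.
#'
#' @param mesh a `tri_mesh` (see [read_mesh()]) or an N x 3 vertex matrix.
#' @param spacing voxel edge length, mm (> 0).
#' @param radius proxy sphere radius, mm (default 0.3).
#' @param source `"upper"` or `"lower"`.
#' @export
mesh_to_sphere_proxies <- function(mesh, spacing, radius = 0.3,
                                   source = c("upper", "lower")) {
  V <- if (inherits(mesh, "tri_mesh")) mesh$vertices else as_point_matrix(mesh)
  if (!nrow(V)) stop("invalid-argument: empty mesh")
  if (!is.finite(spacing) || spacing <= 0)
    stop("invalid-argument: spacing must be > 0")
  cell <- floor(sweep(V, 2L, apply(V, 2, min)) / spacing)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  keep <- !duplicated(key)
  sphere_cloud(V[keep, , drop = FALSE], radius, source = match.arg(source))
}

#' Detect sphere-sphere interference between the arches
#'
#' Applies the mandibular pose to the lower cloud, then reports every
#' upper/lower pair whose center distance falls below the sum of radii.
#' Candidate pairs come from spatial hashing with cell size twice the
#' largest radius; the reported pair set is identical to the all-pairs
#' scan.
#'
#' @param upper,lower `sphere_cloud`s in the articulator frame.
#' @param lower_pose `jaw_pose` applied to the lower cloud (default none).
#' @param ref_condyle reference condyle for the pose, 3-vector mm.
#' @param frame_index index recorded in the report (default 0).
#' @return A `contact_report`: list with `frame_index`, `pairs` (data frame
#'   with `upper_index`, `lower_index`, `penetration_mm`) and
#'   `max_penetration`.
#' @export
detect_collisions <- function(upper, lower, lower_pose = NULL,
                              ref_condyle = c(0, 0, 0), frame_index = 0L) {
  stopifnot(inherits(upper, "sphere_cloud"), inherits(lower, "sphere_cloud"))
  LC <- lower$centers
  if (!is.null(lower_pose)) LC <- apply_jaw_pose(lower_pose, ref_condyle, LC)
  UC <- upper$centers
  ru <- upper$radii; rl <- lower$radii
  cell_size <- 2 * max(ru, rl)
  org <- pmin(apply(UC, 2, min), apply(LC, 2, min))
  ucell <- floor(sweep(UC, 2L, org) / cell_size)
  lcell <- floor(sweep(LC, 2L, org) / cell_size)
  # hash upper spheres into cells; probe the 27-neighbourhood of each lower
  ukey <- paste(ucell[, 1], ucell[, 2], ucell[, 3])
  buckets <- split(seq_len(nrow(UC)), ukey)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  up_idx <- integer(0); lo_idx <- integer(0); pen <- numeric(0)
  for (i in seq_len(nrow(LC))) {
    probe <- sweep(offs, 2L, as.numeric(lcell[i, ]), "+")
    keys <- paste(probe[, 1], probe[, 2], probe[, 3])
    cand <- unlist(buckets[keys], use.names = FALSE)
    if (!length(cand)) next
    d <- sqrt(rowSums((UC[cand, , drop = FALSE] -
                         matrix(LC[i, ], length(cand), 3, byrow = TRUE))^2))
    hit <- d < ru[cand] + rl[i]
    if (any(hit)) {
      up_idx <- c(up_idx, cand[hit])
      lo_idx <- c(lo_idx, rep(i, sum(hit)))
      pen <- c(pen, (ru[cand] + rl[i] - d)[hit])
    }
  }
  ord <- order(up_idx, lo_idx)
  structure(list(frame_index = frame_index,
                 pairs = data.frame(upper_index = up_idx[ord],
                                    lower_index = lo_idx[ord],
                                    penetration_mm = pen[ord]),
                 max_penetration = if (length(pen)) max(pen) else 0),
            class = "contact_report")
}

#' Resolve tooth interference by opening the mandible
#'
#' Bisection on an added inferior (-Z, articulator frame) translation of the
#' pose until the maximum penetration drops to the clearance, or 1 mm of
#' adjustment is exhausted (then an `unresolvable-interference` error is
#' raised carrying the report).
#'
#' @param pose the interfering `jaw_pose`.
#' @param contacts the non-empty `contact_report` at `pose`.
#' @param upper,lower the `sphere_cloud`s used for re-checking.
#' @param ref_condyle reference condyle of the pose, 3-vector mm.
#' @param clearance target maximum penetration, mm (default 0.01).
#' @param max_adjust adjustment budget, mm (default 1).
#' @param tol bisection tolerance on the adjustment, mm (default 1e-4).
#' @return The adjusted `jaw_pose` with attribute `adjustment_mm`.
#' @export
adjust_motion_path <- function(pose, contacts, upper, lower,
                               ref_condyle = c(0, 0, 0), clearance = 0.01,
                               max_adjust = 1, tol = 1e-4) {
  if (!nrow(contacts$pairs))
    stop("invalid-argument: adjust_motion_path requires non-empty contacts")
  shift <- function(delta) {
    p <- pose; p$t_z <- p$t_z - delta
    p
  }
  pen_at <- function(delta)
    detect_collisions(upper, lower, shift(delta), ref_condyle,
                      contacts$frame_index)$max_penetration
  if (contacts$max_penetration <= clearance) {
    out <- pose
    attr(out, "adjustment_mm") <- 0
    return(out)
  }
  if (pen_at(max_adjust) > clearance) {
    e <- simpleError(sprintf(
      "unresolvable-interference: %.3f mm penetration remains after %.1f mm adjustment",
      pen_at(max_adjust), max_adjust))
    e$contact_report <- contacts
    stop(e)
  }
  lo <- 0; hi <- max_adjust
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pen_at(mid) <= clearance) hi <- mid else lo <- mid
  }
  out <- shift(hi)
  attr(out, "adjustment_mm") <- hi
  out
}

#' Dynamic occlusion playback along an incisal guidance path
#'
#' For each sample of the incisal guidance trajectory, solves the
#' constrained mandibular pose by inverse kinematics, checks sphere-proxy
#' interference, and (when penetration exceeds the clearance) opens the
#' mandible with [adjust_motion_path()] before recording the frame. With no
#' sphere clouds supplied the playback degenerates exactly to
#' [trajectory_ik()].
#'
#' @param incisal_guidance `trajectory` of guidance points (articulator
#'   frame).
#' @inheritParams solve_pose
#' @param upper,lower optional `sphere_cloud`s of the dental arches.
#' @param clearance penetration clearance, mm (default 0.01).
#' @return list with `poses` (per-frame `jaw_pose` or `NULL` on IK
#'   failure), `contacts` (per-frame `contact_report` or `NULL`),
#'   `adjusted` (logical per frame) and `solutions`.
#' @export
playback <- function(incisal_guidance, landmarks, path_right, path_left,
                     working_side = c("right", "left"), upper = NULL,
                     lower = NULL, clearance = 0.01) {
  working_side <- match.arg(working_side)
  cw <- if (working_side == "right") landmarks$condyle_right else landmarks$condyle_left
  n <- nrow(incisal_guidance$points)
  poses <- vector("list", n)
  contacts <- vector("list", n)
  adjusted <- logical(n)
  prev <- NULL
  for (i in seq_len(n)) {
    sol <- solve_pose(incisal_guidance$points[i, ], landmarks, path_right,
                      path_left, working_side, initial_guess = prev,
                      error_on_fail = FALSE)
    if (!sol$converged) { prev <- NULL; next }
    prev <- sol$pose
    pose_i <- sol$pose
    if (!is.null(upper) && !is.null(lower)) {
      rep_i <- detect_collisions(upper, lower, pose_i, cw, frame_index = i)
      if (rep_i$max_penetration > clearance) {
        pose_i <- adjust_motion_path(pose_i, rep_i, upper, lower, cw,
                                     clearance = clearance)
        adjusted[i] <- TRUE
        rep_i <- detect_collisions(upper, lower, pose_i, cw, frame_index = i)
      }
      contacts[[i]] <- rep_i
    }
    poses[[i]] <- pose_i
  }
  list(poses = poses, contacts = contacts, adjusted = adjusted)
}
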