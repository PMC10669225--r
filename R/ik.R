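#' Roll angle of the intercondylar line
#'
#' Lateral excursions tilt the line joining the two condyles; the induced
#' rotation about the anterior (Y) axis is recovered from the posed condyle
#' positions as `atan2(zL' - zR', xL' - xR')`, wrapped into (-pi/2, pi/2]
#' so that the value does not depend on which condyle is labeled first.
#'
#' @param right_condyle_after,left_condyle_after posed condyle centers,
#'   3-vectors mm.
#' @return angle in radians in (-pi/2, pi/2].
#' @export
condyle_height_rotation <- function(right_condyle_after, left_condyle_after) {
  dx <- left_condyle_after[1] - right_condyle_after[1]
  dz <- left_condyle_after[3] - right_condyle_after[3]
  if (abs(dx) <= 1e-6)
    stop("degenerate-geometry: condyles coincide in x; roll angle undefined")
  a <- atan2(dz, dx)
  while (a > pi / 2) a <- a - pi
  while (a <= -pi / 2) a <- a + pi
  a
}

# Residual vector of the 6-DOF constraint system, on a raw pose vector
# v = (theta_x, theta_y, theta_z, t_x, t_y, t_z). Mixed units: mm (r1..r5)
# and rad (r6).
ik_residuals_vec <- function(v, incisal_target, landmarks, path_right,
                             path_left, working_side) {
  R <- pose_rot(v)
  cw <- if (working_side == "right") landmarks$condyle_right else landmarks$condyle_left
  tr <- v[4:6] + cw - drop(R %*% cw)
  inc <- drop(R %*% landmarks$incisal_point + tr)
  r13 <- inc - incisal_target
  path <- if (working_side == "right") path_right else path_left
  pw <- evaluate_path(path, cw[2] + v[5], warn = FALSE)
  r4 <- v[4] - (pw$x - cw[1])
  r5 <- v[6] - (pw$z - cw[3])
  cr <- drop(R %*% landmarks$condyle_right + tr)
  cl <- drop(R %*% landmarks$condyle_left + tr)
  r6 <- v[2] - condyle_height_rotation(cr, cl)
  c(r13, r4, r5, r6)
}

#' Residuals of the 6-DOF inverse-kinematics constraint system
#'
#' Components: `r1..r3` the posed incisal point minus the measured target
#' (mm); `r4`, `r5` the working condyle's deviation from the personalized
#' condylar path, `t_x - (f(y0 + t_y) - x0)` and `t_z - (g(y0 + t_y) - z0)`
#' (mm); `r6` the pose's `theta_y` minus the roll angle measured from the
#' posed condyles (rad).
#'
#' @param pose a `jaw_pose`.
#' @param incisal_target measured incisal-edge point, 3-vector mm.
#' @param landmarks `anatomical_landmarks` in the articulator frame.
#' @param path_right,path_left fitted `condylar_path_model`s.
#' @param working_side `"right"` or `"left"`.
#' @return numeric 6-vector.
#' @export
ik_residuals <- function(pose, incisal_target, landmarks, path_right,
                         path_left, working_side = c("right", "left")) {
  working_side <- match.arg(working_side)
  path <- if (working_side == "right") path_right else path_left
  cw <- if (working_side == "right") landmarks$condyle_right else landmarks$condyle_left
  y <- cw[2] + pose$t_y
  if (y < path$y_domain[1] || y > path$y_domain[2])
    warning(warningCondition(
      "IK evaluated outside the fitted condylar-path domain; clamped linear extension used",
      class = "artikin_extrapolation"))
  ik_residuals_vec(pose_vector(pose), incisal_target, landmarks,
                   path_right, path_left, working_side)
}

#' Solve the mandibular pose for a measured incisal point
#'
#' Newton-Raphson on [ik_residuals()] with a central finite-difference
#' Jacobian (step 1e-6) and step-halving damping; convergence when the
#' maximum absolute residual drops below `tol` (mm and rad both).
#'
#' @inheritParams ik_residuals
#' @param initial_guess starting `jaw_pose` (default zero pose).
#' @param tol convergence tolerance on max |residual| (default 1e-8).
#' @param max_iter maximum Newton iterations (default 100).
#' @param error_on_fail raise a `solver-failure` error on non-convergence
#'   (default `TRUE`); otherwise the last iterate is returned with
#'   `converged = FALSE`.
#' @return An `ik_solution`: list with `pose`, `residual_norm`,
#'   `iterations`, `converged`.
#' @export
solve_pose <- function(incisal_target, landmarks, path_right, path_left,
                       working_side = c("right", "left"),
                       initial_guess = NULL, tol = 1e-8, max_iter = 100L,
                       error_on_fail = TRUE) {
  working_side <- match.arg(working_side)
  v <- if (is.null(initial_guess)) rep(0, 6) else pose_vector(initial_guess)
  h <- 1e-6
  res_fun <- function(v)
    ik_residuals_vec(v, incisal_target, landmarks, path_right, path_left,
                     working_side)
  r <- res_fun(v)
  it <- 0L
  converged <- max(abs(r)) < tol
  while (!converged && it < max_iter) {
    it <- it + 1L
    J <- matrix(0, 6, 6)
    for (k in 1:6) {
      vp <- v; vm <- v
      vp[k] <- vp[k] + h; vm[k] <- vm[k] - h
      J[, k] <- (res_fun(vp) - res_fun(vm)) / (2 * h)
    }
    step <- tryCatch(solve(J, r), error = function(e) {
      # damp a singular Jacobian (Levenberg-style ridge)
      solve(J + diag(1e-8, 6), r)
    })
    alpha <- 1
    nr <- sqrt(sum(r^2))
    repeat {
      v_new <- v - alpha * step
      r_new <- res_fun(v_new)
      if (sqrt(sum(r_new^2)) < nr || alpha < 1e-4) break
      alpha <- alpha / 2
    }
    if (sqrt(sum(r_new^2)) >= nr && alpha < 1e-4) break  # stalled
    v <- v_new; r <- r_new
    converged <- max(abs(r)) < tol
  }
  if (any(!is.finite(v))) { v <- rep(0, 6); converged <- FALSE }
  sol <- structure(list(
    pose = vector_pose(v, working_side, angle_bound = Inf),
    residual_norm = max(abs(r)), iterations = it, converged = converged),
    class = "ik_solution")
  if (!converged && error_on_fail)
    stop(sprintf("solver-failure: IK did not converge (max residual %.3g after %d iterations)",
                 sol$residual_norm, it))
  sol
}

#' Inverse kinematics over a whole incisal trajectory
#'
#' Runs [solve_pose()] per sample, warm-started from the previous solution,
#' and maps each solved pose onto the rest condyle centers to obtain the
#' simulated condylar trajectories. Samples whose solver fails are recorded
#' as `NA` rows (gap markers) rather than aborting the trajectory.
#'
#' @param incisal_traj `trajectory` of measured incisal-edge points
#'   (articulator frame).
#' @inheritParams solve_pose
#' @return list with `condyle_right`, `condyle_left` (trajectories) and
#'   `solutions` (list of `ik_solution`, `NULL` where the solver failed).
#' @export
trajectory_ik <- function(incisal_traj, landmarks, path_right, path_left,
                          working_side = c("right", "left"), tol = 1e-8) {
  working_side <- match.arg(working_side)
  stopifnot(inherits(incisal_traj, "trajectory"))
  n <- nrow(incisal_traj$points)
  if (n < 1L) stop("invalid-argument: empty incisal trajectory")
  cw <- if (working_side == "right") landmarks$condyle_right else landmarks$condyle_left
  CR <- matrix(NA_real_, n, 3)
  CL <- matrix(NA_real_, n, 3)
  sols <- vector("list", n)
  prev <- NULL
  withCallingHandlers({
    for (i in seq_len(n)) {
      sol <- solve_pose(incisal_traj$points[i, ], landmarks, path_right,
                        path_left, working_side, initial_guess = prev,
                        tol = tol, error_on_fail = FALSE)
      if (sol$converged) {
        sols[[i]] <- sol
        prev <- sol$pose
        CR[i, ] <- apply_jaw_pose(sol$pose, cw, landmarks$condyle_right)
        CL[i, ] <- apply_jaw_pose(sol$pose, cw, landmarks$condyle_left)
      } else {
        prev <- NULL  # cold-start after a gap
      }
    }
  }, artikin_extrapolation = function(w) invokeRestart("muffleWarning"))
  ok <- !is.na(CR[, 1])
  if (!all(ok))
    warning(sprintf("IK failed on %d of %d samples; gaps marked NA",
                    sum(!ok), n))
  mk <- function(M, lab) {
    tr <- trajectory(incisal_traj$t[ok], M[ok, , drop = FALSE],
                     incisal_traj$frame, lab)
    tr$gap_index <- which(!ok)
    tr
  }
  list(condyle_right = mk(CR, paste0(incisal_traj$label, "/right_condyle_sim")),
       condyle_left = mk(CL, paste0(incisal_traj$label, "/left_condyle_sim")),
       solutions = sols)
}
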