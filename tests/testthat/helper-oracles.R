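# Independent oracles and fixture builders used across the suite.

# Discrete Frechet oracle by threshold decision: the distance is the
# smallest pairwise distance eps for which a monotone coupling using only
# pairs with d <= eps connects (1,1) to (n,m). Reachability is computed by
# fixpoint expansion -- entirely independent of the DP recurrence used by
# the implementation.
frechet_threshold_oracle <- function(P, Q) {
  n <- nrow(P); m <- nrow(Q)
  d <- sqrt(pmax(outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * P %*% t(Q), 0))
  for (eps in sort(unique(as.vector(d)))) {
    ok <- d <= eps
    if (!ok[1, 1]) next
    reach <- matrix(FALSE, n, m)
    reach[1, 1] <- TRUE
    repeat {
      prev <- reach
      up <- matrix(FALSE, n, m); lf <- up; dg <- up
      if (n > 1) up[2:n, ] <- reach[1:(n - 1), ]
      if (m > 1) lf[, 2:m] <- reach[, 1:(m - 1)]
      if (n > 1 && m > 1) dg[2:n, 2:m] <- reach[1:(n - 1), 1:(m - 1)]
      reach <- reach | ((up | lf | dg) & ok)
      if (identical(reach, prev)) break
    }
    if (reach[n, m]) return(eps)
  }
  stop("unreachable")
}

# All-pairs sphere-overlap oracle for collision detection.
all_pairs_collisions <- function(upper, lower, lower_pose = NULL,
                                 ref_condyle = c(0, 0, 0)) {
  LC <- lower$centers
  if (!is.null(lower_pose)) LC <- apply_jaw_pose(lower_pose, ref_condyle, LC)
  out <- NULL
  for (i in seq_len(nrow(upper$centers)))
    for (j in seq_len(nrow(LC))) {
      d <- sqrt(sum((upper$centers[i, ] - LC[j, ])^2))
      if (d < upper$radii[i] + lower$radii[j])
        out <- rbind(out, c(i, j, upper$radii[i] + lower$radii[j] - d))
    }
  if (is.null(out)) data.frame(upper_index = integer(0),
                               lower_index = integer(0),
                               penetration_mm = numeric(0))
  else {
    out <- out[order(out[, 1], out[, 2]), , drop = FALSE]
    data.frame(upper_index = as.integer(out[, 1]),
               lower_index = as.integer(out[, 2]),
               penetration_mm = out[, 3])
  }
}

# Random proper rigid transform (uniform-ish small-to-large rotations).
random_rigid <- function(max_angle = pi, max_shift = 20) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, -max_angle, max_angle)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- stats::runif(3, -max_shift, max_shift)
  framed_transform(m)
}

rotation_error_deg <- function(T_est, T_true) {
  R <- t(T_est$matrix[1:3, 1:3]) %*% T_true$matrix[1:3, 1:3]
  acos(min(1, max(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

# Fit both condylar paths of a patient from (possibly noisy) simulated
# movements and run trajectory IK on a movement's incisal recording.
fit_patient_paths <- function(patient, prot, lat_right, lat_left,
                              clean = FALSE) {
  pick <- function(mov, what) if (clean) mov$clean[[what]] else mov[[what]]
  list(right = fit_condylar_path(pick(prot, "condyle_right"),
                                 pick(lat_right, "condyle_right"), "right"),
       left = fit_condylar_path(pick(prot, "condyle_left"),
                                pick(lat_left, "condyle_left"), "left"))
}
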