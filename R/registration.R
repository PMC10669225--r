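#' Least-squares sphere fit
#'
#' The condyle is nearly spherical, so its center (used as a posterior
#' facebow reference point) is recovered by fitting a sphere to surface
#' points: an algebraic (linearized) least-squares solution refined by
#' Gauss-Newton on the geometric distance `| ||p - c|| - r |`.
#'
#' @param points N x 3 matrix of surface points, mm (>= 4, non-coplanar).
#' @return A `sphere_fit`: list with `center`, `radius`, `rms_error`,
#'   `n_points`.
#' @export
fit_sphere <- function(points) {
  P <- as_point_matrix(points)
  n <- nrow(P)
  if (n < 4L) stop("degenerate-geometry: sphere fit needs >= 4 points")
  A <- cbind(2 * P, 1)
  b <- rowSums(P^2)
  qrA <- qr(A)
  if (qrA$rank < 4L)
    stop("degenerate-geometry: points are coplanar or otherwise degenerate")
  sol <- qr.coef(qrA, b)
  center <- sol[1:3]
  r2 <- sol[4] + sum(center^2)
  if (r2 <= 0) stop("degenerate-geometry: sphere fit collapsed")
  radius <- sqrt(r2)
  # Gauss-Newton refinement of (center, radius) on geometric residuals
  for (iter in 1:20) {
    diffs <- sweep(P, 2L, center)
    dist <- sqrt(rowSums(diffs^2))
    res <- dist - radius
    J <- cbind(-diffs / dist, -1)
    step <- tryCatch(qr.coef(qr(J), res), error = function(e) rep(0, 4))
    step[!is.finite(step)] <- 0
    center <- center - step[1:3]
    radius <- radius - step[4]
    if (max(abs(step)) < 1e-12) break
  }
  dist <- sqrt(rowSums(sweep(P, 2L, center)^2))
  structure(list(center = unname(center), radius = unname(radius),
                 rms_error = sqrt(mean((dist - radius)^2)), n_points = n),
            class = "sphere_fit")
}

#' Build the articulator frame from facebow landmarks (virtual facebow)
#'
#' The hinge axis is the line through the two condyle centers; the origin is
#' its midpoint; +X points toward the right condyle; the reference plane
#' through the three landmarks (Frankfurt when the anterior point is the
#' infraorbital point, Camper when it is the nasal alar point) defines +Z,
#' oriented superior; +Y = Z x X (anterior). Returns the rigid transform
#' taking CT coordinates into the articulator frame, plus the reference
#' plane in CT coordinates.
#'
#' @param condyle_right,condyle_left,anterior_point 3-vectors mm, CT frame.
#' @param kind `"frankfurt"` or `"camper"`.
#' @param up_hint approximate superior direction in the CT frame used to
#'   check the plane-normal orientation (default `c(0, 0, 1)`).
#' @param from_frame name of the input frame (default `"ct"`).
#' @return list with `transform` (`from_frame` -> `"articulator"`) and
#'   `plane` (a `reference_plane`).
#' @export
build_articulator_frame <- function(condyle_right, condyle_left,
                                    anterior_point,
                                    kind = c("frankfurt", "camper"),
                                    up_hint = c(0, 0, 1), from_frame = "ct") {
  kind <- match.arg(kind)
  o <- (condyle_right + condyle_left) / 2
  x_ax <- condyle_right - condyle_left
  nx <- sqrt(sum(x_ax^2))
  if (nx <= 1) stop("degenerate-geometry: condyle centers coincide")
  x_ax <- x_ax / nx
  a_vec <- anterior_point - o
  z_ax <- cross3(x_ax, a_vec)
  nz <- sqrt(sum(z_ax^2))
  # nz/2 is the landmark triangle area per unit hinge length; require > 1 mm^2
  area <- 0.5 * sqrt(sum(cross3(condyle_left - condyle_right,
                                anterior_point - condyle_right)^2))
  if (nz <= 1e-9 || area <= 1)
    stop("degenerate-geometry: landmarks are collinear")
  z_ax <- z_ax / nz
  if (sum(z_ax * up_hint) < 0)
    message("orientation check: reference-plane normal opposes the up hint; ",
            "verify condyle left/right labeling")
  y_ax <- cross3(z_ax, x_ax)
  Rm <- rbind(x_ax, y_ax, z_ax)  # rows: articulator axes in CT coordinates
  m <- diag(4)
  m[1:3, 1:3] <- Rm
  m[1:3, 4] <- -Rm %*% o
  transform <- framed_transform(m, from = from_frame, to = "articulator")
  plane <- structure(list(kind = kind, origin = o, normal = z_ax),
                     class = "reference_plane")
  list(transform = transform, plane = plane)
}

#' Kabsch rigid alignment of paired point sets
#'
#' SVD-based least-squares rigid transform minimizing
#' `sum ||T src_i - dst_i||^2`, with det +1 enforced (the nearest proper
#' rotation is returned even for reflective correspondences).
#'
#' @param src,dst N x 3 matrices of paired points (>= 3, non-collinear).
#' @return A `framed_transform` (frames untagged).
#' @export
kabsch_align <- function(src, dst) {
  S <- as_point_matrix(src); D <- as_point_matrix(dst)
  if (nrow(S) != nrow(D)) stop("invalid-argument: point counts differ")
  if (nrow(S) < 3L) stop("degenerate-geometry: need >= 3 pairs")
  cs <- colMeans(S); cd <- colMeans(D)
  S0 <- sweep(S, 2L, cs); D0 <- sweep(D, 2L, cd)
  H <- crossprod(S0, D0)
  sv <- svd(H)
  if (min(sv$d[1] + sv$d[2], sv$d[2] + sv$d[3]) <= 1e-12 * max(sv$d, 1e-300))
    stop("degenerate-geometry: collinear configuration")
  sgn <- sign(det(sv$v %*% t(sv$u)))
  Rm <- sv$v %*% diag(c(1, 1, sgn)) %*% t(sv$u)
  m <- diag(4)
  m[1:3, 1:3] <- Rm
  m[1:3, 4] <- cd - Rm %*% cs
  framed_transform(m)
}

# exact nearest neighbour in dst for every row of src (Euclidean)
nearest_neighbors <- function(src, dst) {
  d2 <- outer(rowSums(src^2), rowSums(dst^2), "+") - 2 * src %*% t(dst)
  max.col(-d2, ties.method = "first")
}

#' Iterative closest point registration
#'
#' Point-to-point ICP: alternate exact nearest-neighbour correspondence and
#' [kabsch_align()] until the RMS change drops below `tol` or `max_iter`
#' iterations. By default the worst 10% of pairs are trimmed before each
#' alignment. A final RMS above `quality_threshold` sets a quality warning
#' flag in the result (non-overlapping clouds are reported, not raised).
#'
#' @param src_cloud,dst_cloud N x 3 point matrices (>= 10 points each).
#' @param init initial `framed_transform` (default identity).
#' @param trim fraction of worst pairs discarded per iteration (default 0.1).
#' @param tol RMS-change convergence tolerance, mm (default 1e-6).
#' @param max_iter iteration cap (default 50).
#' @param quality_threshold RMS (mm) above which `quality_warning` is set.
#' @return list with `transform`, `rms` (mm), `iterations`, `rms_trace`,
#'   `quality_warning`.
#' @export
icp_register <- function(src_cloud, dst_cloud, init = NULL, trim = 0.1,
                         tol = 1e-6, max_iter = 50L, quality_threshold = 5) {
  S <- as_point_matrix(src_cloud); D <- as_point_matrix(dst_cloud)
  if (nrow(S) < 10L || nrow(D) < 10L)
    stop("invalid-argument: ICP needs >= 10 points per cloud")
  T_cur <- if (is.null(init)) identity_transform() else init
  prev_rms <- Inf; rms <- Inf
  trace <- numeric(0)
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    S_t <- apply_transform(T_cur, S)
    nn <- nearest_neighbors(S_t, D)
    resid <- sqrt(rowSums((S_t - D[nn, , drop = FALSE])^2))
    keep <- seq_len(nrow(S))
    if (trim > 0) {
      n_keep <- max(3L, floor(nrow(S) * (1 - trim)))
      keep <- order(resid)[seq_len(n_keep)]
    }
    T_step <- kabsch_align(S_t[keep, , drop = FALSE],
                           D[nn[keep], , drop = FALSE])
    T_cur <- compose(T_step, T_cur)
    S_t <- apply_transform(T_cur, S)
    nn <- nearest_neighbors(S_t, D)
    rms <- sqrt(mean(rowSums((S_t - D[nn, , drop = FALSE])^2)))
    trace <- c(trace, rms)
    if (abs(prev_rms - rms) < tol) break
    prev_rms <- rms
  }
  list(transform = T_cur, rms = rms, iterations = it, rms_trace = trace,
       quality_warning = rms > quality_threshold)
}

#' Marker pose stream
#'
#' Timestamped pairs of camera->marker transforms from the dual-marker
#' optical tracking of the upper and lower jaw.
#'
#' @param t numeric timestamps, strictly increasing (seconds).
#' @param cam_up,cam_low lists of `framed_transform`s (camera <- marker),
#'   one per timestamp.
#' @export
marker_pose_stream <- function(t, cam_up, cam_low) {
  t <- as.numeric(t)
  if (length(t) && any(diff(t) <= 0))
    stop("invalid-argument: stream timestamps must be strictly increasing")
  if (length(cam_up) != length(t) || length(cam_low) != length(t))
    stop("invalid-argument: transform lists must match timestamp count")
  for (T in c(cam_up, cam_low)) validate_framed_transform(T)
  structure(list(t = t, cam_up = cam_up, cam_low = cam_low),
            class = "marker_pose_stream")
}

#' @export
length.marker_pose_stream <- function(x) length(x$t)

#' Express a lower-jaw point in the articulator frame
#'
#' Composes the marker/camera chain
#' `T_0_up * inv(T_cam_up) * T_cam_low` at the stream sample nearest to
#' time `t` and applies it to a point given in the lower-marker frame.
#' Because only the relative pose of the two markers enters, arbitrary
#' camera motion cancels.
#'
#' @param p_low 3-vector mm in the lower-marker frame.
#' @param t query time, seconds (nearest-sample lookup).
#' @param stream a `marker_pose_stream`.
#' @param T_0_up `framed_transform` upper-marker -> articulator.
#' @export
lower_point_in_articulator <- function(p_low, t, stream, T_0_up) {
  if (!length(stream$t)) stop("invalid-argument: empty pose stream")
  i <- which.min(abs(stream$t - t))
  chain <- compose(compose(T_0_up, invert(stream$cam_up[[i]])),
                   stream$cam_low[[i]])
  apply_transform(chain, p_low)
}

#' Track a lower-jaw landmark through a pose stream
#'
#' Applies [lower_point_in_articulator()] at every stream sample, yielding
#' the landmark's trajectory in the articulator frame.
#'
#' @param landmark_low 3-vector mm in the lower-marker frame.
#' @param stream a `marker_pose_stream`.
#' @param T_0_up `framed_transform` upper-marker -> articulator.
#' @param label trajectory label.
#' @export
track_landmark_trajectory <- function(landmark_low, stream, T_0_up,
                                      label = "") {
  if (!length(stream$t)) stop("invalid-argument: empty pose stream")
  pts <- t(vapply(seq_along(stream$t), function(i) {
    chain <- compose(compose(T_0_up, invert(stream$cam_up[[i]])),
                     stream$cam_low[[i]])
    apply_transform(chain, landmark_low)
  }, numeric(3)))
  trajectory(stream$t, pts, frame = "articulator", label = label)
}
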