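#' Timestamped 3D trajectory
#'
#' Ordered samples of a moving anatomical point (condyle center, incisal
#' edge, ...) in a named frame.
#'
#' @param t numeric timestamps in seconds, non-decreasing.
#' @param points N x 3 numeric matrix of positions in mm.
#' @param frame frame name (default `"articulator"`).
#' @param label free-text label, e.g. `"right_condyle/protrusion/forward/rep1"`.
#' @export
trajectory <- function(t, points, frame = "articulator", label = "") {
  points <- rbind(points)
  if (!is.numeric(points) || ncol(points) != 3L)
    stop("invalid-argument: points must be an N x 3 numeric matrix")
  t <- as.numeric(t)
  if (length(t) != nrow(points))
    stop("invalid-argument: timestamps and points disagree in length")
  if (length(t) && any(diff(t) < 0))
    stop("invalid-argument: timestamps must be non-decreasing")
  if (any(!is.finite(points)) || any(!is.finite(t)))
    stop("invalid-argument: non-finite trajectory data")
  dimnames(points) <- NULL
  structure(list(t = t, points = points, frame = frame, label = label),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory '%s': %d samples in frame '%s'>\n",
              x$label, nrow(x$points), x$frame))
  invisible(x)
}

#' @export
length.trajectory <- function(x) nrow(x$points)

as_point_matrix <- function(x) {
  if (inherits(x, "trajectory")) return(x$points)
  m <- rbind(x)
  stopifnot(is.numeric(m), ncol(m) == 3L)
  m
}

#' Average trajectory error (ATE)
#'
#' Mean point-wise Euclidean distance between index-aligned measured and
#' simulated trajectories: `(1/N) * sum_i ||p_i - q_i||`. Requires equal
#' sample counts; the trajectories are never resampled. With
#' `squared = TRUE` the mean of squared distances is returned instead.
#'
#' @param measured,simulated `trajectory` objects (or N x 3 matrices) with
#'   equal, index-aligned sample counts.
#' @param squared use squared distances (default `FALSE`).
#' @return error in mm (mm^2 when `squared`).
#' @export
average_trajectory_error <- function(measured, simulated, squared = FALSE) {
  P <- as_point_matrix(measured); Q <- as_point_matrix(simulated)
  if (nrow(P) != nrow(Q))
    stop("invalid-argument: ATE requires equal sample counts (no resampling)")
  if (nrow(P) < 1L) stop("invalid-argument: empty trajectory")
  d2 <- rowSums((P - Q)^2)
  if (squared) mean(d2) else mean(sqrt(d2))
}

#' Discrete Frechet distance between two polygonal chains
#'
#' Iterative Eiter-Mannila dynamic program:
#' `c(i,j) = max(d(P_i, Q_j), min(c(i-1,j), c(i-1,j-1), c(i,j-1)))` with
#' Euclidean `d`; the returned value is the minimum over all monotone
#' couplings of the maximum pairwise distance.
#'
#' @param P,Q `trajectory` objects or N x 3 matrices (non-empty).
#' @return distance in mm.
#' @export
discrete_frechet <- function(P, Q) {
  A <- as_point_matrix(P); B <- as_point_matrix(Q)
  n <- nrow(A); m <- nrow(B)
  if (n < 1L || m < 1L) stop("invalid-argument: empty chain")
  # pairwise distance matrix, vectorized
  d <- sqrt(pmax(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B), 0))
  ca <- matrix(0, n, m)
  ca[1, 1] <- d[1, 1]
  for (i in seq_len(n)[-1]) ca[i, 1] <- max(ca[i - 1, 1], d[i, 1])
  for (j in seq_len(m)[-1]) ca[1, j] <- max(ca[1, j - 1], d[1, j])
  if (n > 1L && m > 1L)
    for (i in 2:n) for (j in 2:m)
      ca[i, j] <- max(d[i, j], min(ca[i - 1, j], ca[i - 1, j - 1], ca[i, j - 1]))
  ca[n, m]
}

#' Split an out-and-back recording into forward/backward repetitions
#'
#' Movements are recorded from the centric-occlusion (rest) position to the
#' extreme position and back, possibly repeated. This splits the recording
#' at the local extrema of distance-from-rest into alternating `forward`
#' (rest -> extreme) and `backward` (extreme -> rest) segments labeled
#' `rep1, rep2, ...`.
#'
#' @param traj a `trajectory` starting near `rest_point`.
#' @param rest_point 3-vector mm.
#' @param start_tol maximum allowed start offset from rest (mm, default 1).
#' @return named list of `trajectory` segments, names `forward/rep1`,
#'   `backward/rep1`, `forward/rep2`, ...
#' @export
split_repetitions <- function(traj, rest_point, start_tol = 1) {
  stopifnot(inherits(traj, "trajectory"))
  P <- traj$points
  n <- nrow(P)
  d <- sqrt(colSums((t(P) - rest_point)^2))
  if (d[1] > start_tol)
    stop(sprintf("invalid-argument: trajectory starts %.2f mm from rest (tol %.2f)",
                 d[1], start_tol))
  w <- max(3L, n %/% 10L)
  amp <- max(d)
  is_ext <- function(i, cmp) {
    lo <- max(1L, i - w); hi <- min(n, i + w)
    cmp(d[i], d[lo:hi])
  }
  peaks <- integer(0)
  i <- 1L + w
  while (i <= n - 1L) {
    if (d[i] >= max(d[max(1L, i - w):min(n, i + w)]) && d[i] > amp / 2) {
      peaks <- c(peaks, i)
      i <- i + w  # skip the plateau around this peak
    }
    i <- i + 1L
  }
  if (!length(peaks)) {
    warning("no extreme position found; returning a single forward segment")
    return(stats::setNames(
      list(trajectory(traj$t, P, traj$frame, paste0(traj$label, "/forward/rep1"))),
      "forward/rep1"))
  }
  # valleys (returns to rest) between successive peaks, plus the end
  cuts <- integer(0)
  if (length(peaks) > 1L)
    for (k in seq_len(length(peaks) - 1L)) {
      span <- peaks[k]:peaks[k + 1L]
      cuts <- c(cuts, span[which.min(d[span])])
    }
  bounds <- sort(unique(c(1L, peaks, cuts, n)))
  segs <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    idx <- bounds[k]:bounds[k + 1L]
    dir <- if (d[bounds[k + 1L]] >= d[bounds[k]]) "forward" else "backward"
    rep_no <- sum(vapply(segs, function(s) s$dir == dir, logical(1))) + 1L
    segs[[length(segs) + 1L]] <-
      list(dir = dir, rep = rep_no,
           traj = trajectory(traj$t[idx], P[idx, , drop = FALSE], traj$frame,
                             sprintf("%s/%s/rep%d", traj$label, dir, rep_no)))
  }
  out <- lapply(segs, `[[`, "traj")
  names(out) <- vapply(segs, function(s) sprintf("%s/rep%d", s$dir, s$rep),
                       character(1))
  out
}

#' Compare tracked and simulated trajectories movement by movement
#'
#' Computes the discrete Frechet distance per matching label, per-direction
#' averages over repetitions, and the grand mean over all individual cells
#' (the layout of the verification table: movement x condyle x direction x
#' repetition).
#'
#' Labels must follow `movement/condyle/direction/repN` (e.g.
#' `"protrusion/right_condyle/forward/rep1"`), and both inputs must carry
#' the same label set.
#'
#' @param tracked,simulated named lists of `trajectory` objects with
#'   matching names.
#' @return A `trajectory_comparison`: list with `per_segment` (named
#'   distances, mm), `cells` (long data frame), `averages` (per
#'   movement/condyle/direction) and `grand_mean` (mm).
#' @export
compare_movement <- function(tracked, simulated) {
  labs <- names(tracked)
  if (is.null(labs) || !setequal(labs, names(simulated)))
    stop(sprintf("invalid-argument: unmatched labels: %s",
                 paste(union(setdiff(labs, names(simulated)),
                             setdiff(names(simulated), labs)),
                       collapse = ", ")))
  per <- vapply(labs, function(l) discrete_frechet(tracked[[l]], simulated[[l]]),
                numeric(1))
  parts <- strsplit(labs, "/", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad))
    stop(sprintf("invalid-argument: label '%s' is not movement/condyle/direction/repN",
                 labs[bad][1]))
  cells <- data.frame(movement = vapply(parts, `[`, "", 1L),
                      condyle = vapply(parts, `[`, "", 2L),
                      direction = vapply(parts, `[`, "", 3L),
                      repetition = vapply(parts, `[`, "", 4L),
                      frechet_mm = unname(per),
                      stringsAsFactors = FALSE)
  averages <- stats::aggregate(frechet_mm ~ movement + condyle + direction,
                               data = cells, FUN = mean)
  structure(list(per_segment = per, cells = cells, averages = averages,
                 grand_mean = mean(cells$frechet_mm)),
            class = "trajectory_comparison")
}

#' @export
print.trajectory_comparison <- function(x, ...) {
  cat("<trajectory_comparison>\n")
  print(x$averages)
  cat(sprintf("grand mean: %.2f mm over %d cells\n",
              x$grand_mean, nrow(x$cells)))
  invisible(x)
}

#' Write a comparison report as CSV
#'
#' Long-format report mirroring the verification table: one row per
#' movement x condyle x direction x repetition cell, followed by the
#' per-direction averages and the grand mean, all at 2 decimals (mm).
#'
#' @param comparison a `trajectory_comparison`.
#' @param path output CSV path.
#' @export
write_comparison_csv <- function(comparison, path) {
  cells <- comparison$cells
  cells$frechet_mm <- sprintf("%.2f", cells$frechet_mm)
  avg <- comparison$averages
  avg_rows <- data.frame(movement = avg$movement, condyle = avg$condyle,
                         direction = avg$direction, repetition = "average",
                         frechet_mm = sprintf("%.2f", avg$frechet_mm),
                         stringsAsFactors = FALSE)
  grand <- data.frame(movement = "all", condyle = "all", direction = "all",
                      repetition = "grand_mean",
                      frechet_mm = sprintf("%.2f", comparison$grand_mean),
                      stringsAsFactors = FALSE)
  utils::write.csv(rbind(cells, avg_rows, grand), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
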