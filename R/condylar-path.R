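#' Personalized condylar-path model
#'
#' Per-side model of the condyle's border path, fitted from tracked condylar
#' trajectories. Three coupled representations are kept:
#' a sagittal-plane quadratic `z = a*y^2 + b*y + c` (carrying the condylar
#' inclination), a horizontal-plane line `x = m*y + k` (carrying the Bennett
#' angle), and a clamped cubic NURBS curve through the 3D protrusion samples
#' for visualization/export. The inverse kinematics consumes the scalar
#' functions `f(y) = x`, `g(y) = z` from the planar fits.
#'
#' @name condylar_path_model
NULL

new_condylar_path_model <- function(side, sagittal_coeffs, horizontal_coeffs,
                                    bennett_angle, inclination_angle,
                                    y_domain, nurbs = NULL,
                                    sagittal_rms = 0, horizontal_rms = 0) {
  if (y_domain[1] >= y_domain[2])
    stop("invalid-argument: y_domain must satisfy y_min < y_max")
  structure(list(side = side,
                 sagittal_coeffs = sagittal_coeffs,    # c(a, b, c)
                 horizontal_coeffs = horizontal_coeffs, # c(m, k)
                 bennett_angle = bennett_angle,         # degrees
                 inclination_angle = inclination_angle, # degrees
                 y_domain = y_domain,
                 nurbs = nurbs,
                 sagittal_rms = sagittal_rms,
                 horizontal_rms = horizontal_rms),
            class = "condylar_path_model")
}

#' Sagittal quadratic fit of a condylar protrusion path
#'
#' Projects condyle trajectory samples onto the sagittal plane (their (y, z)
#' coordinates) and fits `z = a*y^2 + b*y + c` by ordinary least squares.
#' The condylar inclination is reported as `atan(|dz/dy|)` at the rest point
#' (the first sample), in degrees relative to the reference plane z = 0.
#'
#' @param points N x 3 matrix or `trajectory` of condyle samples
#'   (articulator frame, mm).
#' @return list with `a`, `b`, `c`, `rms` (mm) and `inclination` (degrees).
#' @export
fit_sagittal_quadratic <- function(points) {
  P <- as_point_matrix(points)
  y <- P[, 2]; z <- P[, 3]
  if (length(unique(round(y, 9))) < 3L)
    stop("insufficient-data: need >= 3 samples with distinct y")
  fit <- stats::lm.fit(cbind(y^2, y, 1), z)
  cf <- unname(fit$coefficients)
  y_rest <- y[1]
  slope <- 2 * cf[1] * y_rest + cf[2]
  list(a = cf[1], b = cf[2], c = cf[3],
       rms = sqrt(mean(fit$residuals^2)),
       inclination = atan(abs(slope)) * 180 / pi)
}

#' Horizontal line fit of a working-side lateral excursion
#'
#' Projects lateral-excursion samples of the working-side condyle onto the
#' horizontal plane and fits `x = m*y + k`; the Bennett angle is
#' `atan(|m|)` in degrees.
#'
#' @param points N x 3 matrix or `trajectory` of working-side condyle samples.
#' @return list with `m`, `k`, `rms` (mm) and `bennett_angle` (degrees).
#' @export
fit_horizontal_line <- function(points) {
  P <- as_point_matrix(points)
  y <- P[, 2]; x <- P[, 1]
  if (length(unique(round(y, 9))) < 2L)
    stop("insufficient-data: need >= 2 samples with distinct y")
  fit <- stats::lm.fit(cbind(y, 1), x)
  cf <- unname(fit$coefficients)
  list(m = cf[1], k = cf[2],
       rms = sqrt(mean(fit$residuals^2)),
       bennett_angle = atan(abs(cf[1])) * 180 / pi)
}

#' Cox-de Boor B-spline basis function
#'
#' Value of the j-th (zero-based) basis function of degree `p` on the knot
#' vector `knots`, with the 0/0 convention resolved to 0. At the right end
#' of the domain the last basis function evaluates to 1 (clamped convention).
#'
#' @param u parameter value within the knot range.
#' @param j zero-based basis index.
#' @param p degree.
#' @param knots non-decreasing knot vector.
#' @export
nurbs_basis <- function(u, j, p, knots) {
  n_basis <- length(knots) - p - 1L
  if (j < 0L || j > n_basis - 1L)
    stop("invalid-argument: basis index out of range")
  u_min <- knots[p + 1L]; u_max <- knots[length(knots) - p]
  if (u < u_min - 1e-12 || u > u_max + 1e-12)
    stop("invalid-argument: parameter outside the knot range")
  # closed clamped end: treat u == u_max as belonging to the last span
  if (u >= u_max) {
    if (p == 0L) return(as.numeric(j == n_basis - 1L))
  }
  basis_rec <- function(j, p) {
    if (p == 0L) {
      if (u >= u_max)
        return(as.numeric(knots[j + 1L] < u_max && knots[j + 2L] >= u_max))
      return(as.numeric(u >= knots[j + 1L] && u < knots[j + 2L]))
    }
    d1 <- knots[j + p + 1L] - knots[j + 1L]
    d2 <- knots[j + p + 2L] - knots[j + 2L]
    t1 <- if (d1 > 0) (u - knots[j + 1L]) / d1 * basis_rec(j, p - 1L) else 0
    t2 <- if (d2 > 0) (knots[j + p + 2L] - u) / d2 * basis_rec(j + 1L, p - 1L) else 0
    t1 + t2
  }
  basis_rec(j, p)
}

# Clamped knot vector for least-squares fitting (knot averaging over the
# parameter values, Piegl & Tiller style placement).
lsq_knot_vector <- function(u, n_ctrl, p) {
  m <- length(u)
  n_int <- n_ctrl - p - 1L
  interior <- numeric(0)
  if (n_int > 0) {
    d <- m / (n_ctrl - p)
    interior <- vapply(seq_len(n_int), function(j) {
      i <- floor(j * d); alpha <- j * d - i
      (1 - alpha) * u[max(i, 1L)] + alpha * u[min(i + 1L, m)]
    }, numeric(1))
  }
  c(rep(u[1], p + 1L), interior, rep(u[m], p + 1L))
}

#' Fit the personalized condylar path
#'
#' Runs the sagittal quadratic fit on the protrusion trajectory and the
#' horizontal line fit on the lateral-excursion trajectory of the same side,
#' then fits a clamped cubic NURBS curve (uniform weights, chord-length
#' parameterization, least-squares control points) through the 3D protrusion
#' samples. The number of control points is `max(4, ceiling(N/5))`, capped
#' at 25.
#'
#' @param protrusion,lateral condyle `trajectory` objects (or N x 3
#'   matrices) in the articulator frame for this side.
#' @param side `"right"` or `"left"`.
#' @param degree NURBS degree (default 3).
#' @return A `condylar_path_model`.
#' @export
fit_condylar_path <- function(protrusion, lateral, side = c("right", "left"),
                              degree = 3L) {
  side <- match.arg(side)
  P <- as_point_matrix(protrusion)
  if (nrow(P) < 4L)
    stop("insufficient-data: protrusion path needs >= 4 samples")
  sag <- fit_sagittal_quadratic(P)
  hor <- fit_horizontal_line(lateral)

  # chord-length parameterization on [0, 1]
  seg <- sqrt(rowSums(diff(P)^2))
  u <- c(0, cumsum(seg))
  if (u[length(u)] == 0) stop("insufficient-data: degenerate protrusion path")
  u <- u / u[length(u)]
  n_ctrl <- min(25L, max(4L, as.integer(ceiling(nrow(P) / 5))))
  n_ctrl <- min(n_ctrl, nrow(P))
  knots <- lsq_knot_vector(u, n_ctrl, degree)
  B <- vapply(seq_len(n_ctrl) - 1L,
              function(j) vapply(u, nurbs_basis, numeric(1), j = j,
                                 p = degree, knots = knots),
              numeric(length(u)))
  ctrl <- qr.coef(qr(B), P)
  nurbs <- list(degree = as.integer(degree), control_points = ctrl,
                weights = rep(1, n_ctrl), knots = knots)

  new_condylar_path_model(
    side = side,
    sagittal_coeffs = c(a = sag$a, b = sag$b, c = sag$c),
    horizontal_coeffs = c(m = hor$m, k = hor$k),
    bennett_angle = hor$bennett_angle,
    inclination_angle = sag$inclination,
    y_domain = range(P[, 2]),
    nurbs = nurbs,
    sagittal_rms = sag$rms, horizontal_rms = hor$rms)
}

#' Construct a condylar-path model from known coefficients
#'
#' Used by the synthetic-patient generator to carry exact ground-truth paths.
#'
#' @param side `"right"` or `"left"`.
#' @param sagittal numeric `c(a, b, c)` of `z = a*y^2 + b*y + c`.
#' @param horizontal numeric `c(m, k)` of `x = m*y + k`.
#' @param y_domain numeric `c(y_min, y_max)` in mm.
#' @param rest_y y-coordinate of the rest condyle, where the inclination is
#'   evaluated (default `y_domain[1]`).
#' @export
condylar_path_from_coeffs <- function(side, sagittal, horizontal, y_domain,
                                      rest_y = y_domain[1]) {
  slope <- 2 * sagittal[1] * rest_y + sagittal[2]
  new_condylar_path_model(
    side = side,
    sagittal_coeffs = c(a = sagittal[1], b = sagittal[2], c = sagittal[3]),
    horizontal_coeffs = c(m = horizontal[1], k = horizontal[2]),
    bennett_angle = atan(abs(horizontal[1])) * 180 / pi,
    inclination_angle = atan(abs(slope)) * 180 / pi,
    y_domain = as.numeric(y_domain))
}

#' Evaluate the planar path functions f(y), g(y)
#'
#' The IK-facing representation of the condylar path: for a condyle anterior
#' advance to ordinate `y`, returns the lateral position `x = f(y)` from the
#' horizontal line fit and the vertical position `z = g(y)` from the
#' sagittal quadratic. Outside the fitted y-domain the curves are continued
#' linearly from the nearest endpoint with an `artikin_extrapolation`
#' warning.
#'
#' @param model a `condylar_path_model`.
#' @param y ordinate(s), mm.
#' @param warn emit the extrapolation warning (default `TRUE`).
#' @return list with numeric `x` and `z` of the same length as `y`.
#' @export
evaluate_path <- function(model, y, warn = TRUE) {
  if (!inherits(model, "condylar_path_model"))
    stop("invalid-state: not a fitted condylar_path_model")
  sc <- model$sagittal_coeffs; hc <- model$horizontal_coeffs
  lo <- model$y_domain[1]; hi <- model$y_domain[2]
  out_lo <- y < lo; out_hi <- y > hi
  if (warn && any(out_lo | out_hi))
    warning(warningCondition(
      sprintf("condylar path evaluated outside fitted domain [%.3f, %.3f]; linear extension used",
              lo, hi),
      class = "artikin_extrapolation"))
  yc <- pmin(pmax(y, lo), hi)
  z <- sc[1] * yc^2 + sc[2] * yc + sc[3]
  x <- hc[1] * yc + hc[2]
  # first-order continuation beyond the endpoints
  dz <- 2 * sc[1] * yc + sc[2]
  ext <- y - yc
  z <- z + dz * ext
  x <- x + hc[1] * ext
  list(x = unname(x), z = unname(z))
}

#' Evaluate the fitted NURBS curve
#'
#' Rational B-spline point at parameter `u` in [0, 1]; with uniform weights
#' this is the plain B-spline.
#'
#' @param model a `condylar_path_model` with a fitted NURBS component.
#' @param u parameter in [0, 1].
#' @return 3-vector mm.
#' @export
evaluate_nurbs <- function(model, u) {
  nb <- model$nurbs
  if (is.null(nb)) stop("invalid-state: model has no fitted NURBS component")
  if (!is.finite(u) || u < 0 || u > 1)
    stop("invalid-argument: NURBS parameter must lie in [0, 1]")
  uu <- nb$knots[1] + u * (nb$knots[length(nb$knots)] - nb$knots[1])
  n_ctrl <- nrow(nb$control_points)
  N <- vapply(seq_len(n_ctrl) - 1L, nurbs_basis, numeric(1),
              u = uu, p = nb$degree, knots = nb$knots)
  wN <- N * nb$weights
  drop(crossprod(wN, nb$control_points)) / sum(wN)
}

#' Serialize / read a condylar-path model as JSON
#' @param model a `condylar_path_model`.
#' @param path file path.
#' @export
write_path_json <- function(model, path) {
  x <- list(side = model$side,
            sagittal_coeffs = unname(as.numeric(model$sagittal_coeffs)),
            horizontal_coeffs = unname(as.numeric(model$horizontal_coeffs)),
            bennett_angle_deg = model$bennett_angle,
            inclination_angle_deg = model$inclination_angle,
            y_domain_mm = model$y_domain,
            sagittal_rms_mm = model$sagittal_rms,
            horizontal_rms_mm = model$horizontal_rms)
  if (!is.null(model$nurbs))
    x$nurbs <- list(degree = model$nurbs$degree,
                    control_points = apply(model$nurbs$control_points, 1,
                                           as.numeric, simplify = FALSE),
                    weights = as.numeric(model$nurbs$weights),
                    knots = as.numeric(model$nurbs$knots))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_path_json
#' @export
read_path_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  nurbs <- NULL
  if (!is.null(x$nurbs))
    nurbs <- list(degree = as.integer(x$nurbs$degree),
                  control_points = as_row_matrix(x$nurbs$control_points),
                  weights = as.numeric(x$nurbs$weights),
                  knots = as.numeric(x$nurbs$knots))
  new_condylar_path_model(
    side = x$side,
    sagittal_coeffs = as.numeric(x$sagittal_coeffs),
    horizontal_coeffs = as.numeric(x$horizontal_coeffs),
    bennett_angle = x$bennett_angle_deg,
    inclination_angle = x$inclination_angle_deg,
    y_domain = as.numeric(x$y_domain_mm),
    nurbs = nurbs,
    sagittal_rms = x$sagittal_rms_mm, horizontal_rms = x$horizontal_rms_mm)
}
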