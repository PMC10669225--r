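# Condylar-path personalization: planar fits and NURBS curve.

test_that("sagittal quadratic fit interpolates exact data", {
  y <- seq(0, 8, length.out = 20)
  pts <- cbind(50, y, 0.02 * y^2 - 0.6 * y + 3)
  fit <- fit_sagittal_quadratic(pts)
  expect_equal(c(fit$a, fit$b, fit$c), c(0.02, -0.6, 3), tolerance = 1e-9)
  expect_equal(fit$inclination, atan(0.6) * 180 / pi, tolerance = 1e-9)
  # horizontal path: zero coefficients, zero inclination
  flat <- cbind(50, y, 2)
  ffit <- fit_sagittal_quadratic(flat)
  expect_equal(c(ffit$a, ffit$b), c(0, 0), tolerance = 1e-12)
  expect_equal(ffit$inclination, 0)
  expect_error(fit_sagittal_quadratic(pts[c(1, 1, 1), ]), "insufficient-data")
})

test_that("horizontal line fit recovers the Bennett angle", {
  y <- seq(0, 3, length.out = 15)
  pts <- cbind(tan(15 * pi / 180) * y + 55, y, -1)
  fit <- fit_horizontal_line(pts)
  expect_equal(fit$bennett_angle, 15, tolerance = 1e-9)
  sag <- cbind(55, y, -1)  # purely sagittal motion
  expect_equal(fit_horizontal_line(sag)$bennett_angle, 0)
  expect_error(fit_horizontal_line(pts[c(2, 2), ]), "insufficient-data")
})

test_that("planar-fit angle recovery tolerates tracking noise", {
  # seeded Monte-Carlo against known ground truth
  errs <- t(vapply(1:25, function(s) {
    pat <- generate_patient(500 + s, overrides = list(noise_sigma = 0.1))
    prot <- simulate_movement(pat, "protrusion", n_samples = 50)
    lat <- simulate_movement(pat, "right_excursion", n_samples = 50)
    fit <- fit_condylar_path(prot$condyle_right, lat$condyle_right, "right")
    c(abs(fit$bennett_angle - pat$bennett_deg),
      abs(fit$inclination_angle - pat$inclination_deg))
  }, numeric(2)))
  expect_lt(stats::median(errs[, 1]), 0.5)
  expect_lt(stats::median(errs[, 2]), 0.5)
})

test_that("angle estimates are invariant to uniform time-resampling", {
  pat <- generate_patient(77)
  prot <- simulate_movement(pat, "protrusion", n_samples = 24, cycles = 1)
  lat <- simulate_movement(pat, "right_excursion", n_samples = 24, cycles = 1)
  thin <- function(tr) trajectory(tr$t[c(TRUE, FALSE)],
                                  tr$points[c(TRUE, FALSE), ], tr$frame)
  full <- fit_condylar_path(prot$clean$condyle_right,
                            lat$clean$condyle_right, "right")
  sub <- fit_condylar_path(thin(prot$clean$condyle_right),
                           thin(lat$clean$condyle_right), "right")
  expect_equal(sub$bennett_angle, full$bennett_angle, tolerance = 1e-6)
  expect_equal(sub$inclination_angle, full$inclination_angle, tolerance = 1e-6)
})

test_that("basis functions satisfy Cox-de Boor properties", {
  knots <- c(0, 0, 0, 0, 0.3, 0.7, 1, 1, 1, 1)
  # degree 0: indicator of its knot span
  expect_equal(nurbs_basis(0.5, 4, 0, knots), 1)
  expect_equal(nurbs_basis(0.2, 4, 0, knots), 0)
  # partition of unity at many parameters, degree 3
  for (u in c(0, 0.123, 0.3, 0.456, 0.7, 0.99, 1)) {
    s <- sum(vapply(0:5, nurbs_basis, numeric(1), u = u, p = 3, knots = knots))
    expect_equal(s, 1, tolerance = 1e-12)
  }
  # independent textbook recursion oracle at a midpoint
  oracle <- function(u, j, p, kn) {
    if (p == 0) return(as.numeric(u >= kn[j + 1] & u < kn[j + 2]))
    a <- if (kn[j + p + 1] > kn[j + 1])
      (u - kn[j + 1]) / (kn[j + p + 1] - kn[j + 1]) * oracle(u, j, p - 1, kn)
    else 0
    b <- if (kn[j + p + 2] > kn[j + 2])
      (kn[j + p + 2] - u) / (kn[j + p + 2] - kn[j + 2]) * oracle(u, j + 1, p - 1, kn)
    else 0
    a + b
  }
  for (j in 0:5)
    expect_equal(nurbs_basis(0.456, j, 3, knots), oracle(0.456, j, 3, knots),
                 tolerance = 1e-12)
  expect_error(nurbs_basis(1.2, 0, 3, knots), "invalid-argument")
})

test_that("fitted path model reproduces its generator", {
  pat <- generate_patient(8)
  prot <- simulate_movement(pat, "protrusion", n_samples = 20, cycles = 1)
  lat <- simulate_movement(pat, "right_excursion", n_samples = 20, cycles = 1)
  model <- fit_condylar_path(prot$clean$condyle_right,
                             lat$clean$condyle_right, "right")
  y <- seq(model$y_domain[1], model$y_domain[2], length.out = 30)
  got <- evaluate_path(model, y)
  truth <- evaluate_path(pat$true_paths$right, y)
  expect_lt(max(abs(got$x - truth$x)), 1e-6)
  expect_lt(max(abs(got$z - truth$z)), 1e-6)
  # rest condyle is on the path within the fit rms
  rest <- evaluate_path(model, pat$landmarks$condyle_right[2])
  expect_lt(abs(rest$x - pat$landmarks$condyle_right[1]),
            model$horizontal_rms + 1e-9)
  expect_lt(abs(rest$z - pat$landmarks$condyle_right[3]),
            model$sagittal_rms + 1e-9)
  expect_error(fit_condylar_path(prot$clean$condyle_right$points[1:2, ],
                                 lat$clean$condyle_right, "right"),
               "insufficient-data")
})

test_that("cubic NURBS reproduces a straight 3D segment exactly", {
  t <- seq(0, 1, length.out = 12)
  line <- cbind(1 + 2 * t, -3 + 4 * t, 5 - 6 * t)
  lat <- cbind(1 + 0.2 * t, -3 + t, 5)
  model <- fit_condylar_path(line, lat, "right")
  for (u in c(0, 0.25, 0.5, 0.77, 1)) {
    expected <- c(1, -3, 5) + u * c(2, 4, -6)
    # chord-length parameter is proportional to arclength on a line
    expect_equal(evaluate_nurbs(model, u), expected, tolerance = 1e-6)
  }
  expect_equal(evaluate_nurbs(model, 0), model$nurbs$control_points[1, ])
  expect_equal(evaluate_nurbs(model, 1),
               model$nurbs$control_points[nrow(model$nurbs$control_points), ])
  expect_error(evaluate_nurbs(model, 1.5), "invalid-argument")
})

test_that("rational evaluation matches the direct weighted summation", {
  pat <- generate_patient(12)
  prot <- simulate_movement(pat, "protrusion", n_samples = 20, cycles = 1)
  lat <- simulate_movement(pat, "right_excursion", n_samples = 10, cycles = 1)
  model <- fit_condylar_path(prot$clean$condyle_right,
                             lat$clean$condyle_right, "right")
  set.seed(99)
  model$nurbs$weights <- stats::runif(nrow(model$nurbs$control_points), 0.5, 2)
  for (u in stats::runif(5)) {
    N <- vapply(seq_along(model$nurbs$weights) - 1L, nurbs_basis, numeric(1),
                u = model$nurbs$knots[1] +
                  u * diff(range(model$nurbs$knots)),
                p = model$nurbs$degree, knots = model$nurbs$knots)
    direct <- colSums(N * model$nurbs$weights * model$nurbs$control_points) /
      sum(N * model$nurbs$weights)
    expect_equal(evaluate_nurbs(model, u), direct, tolerance = 1e-12)
  }
  # convex-hull property of positive-weight rational curves
  hull_lo <- apply(model$nurbs$control_points, 2, min) - 1e-9
  hull_hi <- apply(model$nurbs$control_points, 2, max) + 1e-9
  for (u in stats::runif(20)) {
    p <- evaluate_nurbs(model, u)
    expect_true(all(p >= hull_lo & p <= hull_hi))
  }
})

test_that("path evaluation extends linearly outside the fitted domain", {
  model <- condylar_path_from_coeffs("right", sagittal = c(0.05, -0.7, 1),
                                     horizontal = c(0.2, 55),
                                     y_domain = c(0, 5))
  # symbolic endpoint continuation: slope 2a*5 + b at the high end
  expect_warning(out <- evaluate_path(model, 7), class = "artikin_extrapolation")
  z5 <- 0.05 * 25 - 0.7 * 5 + 1
  expect_equal(out$z, z5 + (2 * 0.05 * 5 - 0.7) * 2, tolerance = 1e-12)
  expect_equal(out$x, 0.2 * 7 + 55, tolerance = 1e-12)
  inside <- evaluate_path(model, 2.5)
  expect_equal(inside$z, 0.05 * 2.5^2 - 0.7 * 2.5 + 1, tolerance = 1e-12)
})

test_that("path model JSON round-trips", {
  pat <- generate_patient(21)
  prot <- simulate_movement(pat, "protrusion", n_samples = 15, cycles = 1)
  lat <- simulate_movement(pat, "left_excursion", n_samples = 15, cycles = 1)
  model <- fit_condylar_path(prot$clean$condyle_left,
                             lat$clean$condyle_left, "left")
  path <- withr::local_tempfile(fileext = ".json")
  write_path_json(model, path)
  back <- read_path_json(path)
  expect_equal(back$sagittal_coeffs, unname(model$sagittal_coeffs))
  expect_equal(back$bennett_angle, model$bennett_angle)
  expect_equal(back$nurbs$control_points, unname(model$nurbs$control_points))
  y <- seq(model$y_domain[1], model$y_domain[2], length.out = 7)
  expect_equal(evaluate_path(back, y), evaluate_path(model, y))
})
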