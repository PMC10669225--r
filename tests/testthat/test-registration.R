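# Virtual facebow, sphere fitting, rigid registration, marker chain.

test_that("sphere fit recovers exact and degenerate inputs", {
  axes <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  fit <- fit_sphere(axes)
  expect_equal(fit$center, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(fit$radius, 1, tolerance = 1e-12)
  # hemisphere samples of a known sphere, zero noise
  pat <- generate_patient(9)
  pts <- sample_condyle_surface(pat, "left", 60, noise_sigma = 0)
  fit <- fit_sphere(pts)
  expect_equal(fit$center, pat$landmarks$condyle_left, tolerance = 1e-9)
  expect_equal(fit$radius, pat$condyle_radius, tolerance = 1e-9)
  expect_lt(fit$rms_error, 1e-9)
  # coplanar points are rejected
  flat <- cbind(matrix(stats::rnorm(8), 4, 2), 0)
  expect_error(fit_sphere(flat), "degenerate-geometry")
  expect_error(fit_sphere(axes[1:3, ]), "degenerate-geometry")
})

test_that("noisy condyle surfaces still localize the center", {
  errs <- vapply(1:30, function(s) {
    pat <- generate_patient(1000 + s)
    pts <- sample_condyle_surface(pat, "right", 500, noise_sigma = 0.1)
    sqrt(sum((fit_sphere(pts)$center - pat$landmarks$condyle_right)^2))
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
})

test_that("articulator frame construction undoes an arbitrary CT pose", {
  # canonical landmarks are already in articulator pose -> identity
  fr <- build_articulator_frame(c(55, 0, 0), c(-55, 0, 0), c(0, 80, 0))
  expect_equal(fr$transform$matrix, diag(4), tolerance = 1e-12)
  expect_equal(fr$plane$normal, c(0, 0, 1), tolerance = 1e-12)
  # apply-then-recover oracle under random rigid poses
  set.seed(23)
  for (k in 1:10) {
    G <- random_rigid()
    fr2 <- build_articulator_frame(apply_transform(G, c(55, 0, 0)),
                                   apply_transform(G, c(-55, 0, 0)),
                                   apply_transform(G, c(0, 80, 0)),
                                   up_hint = apply_transform(G, c(0, 0, 1)) -
                                     apply_transform(G, c(0, 0, 0)))
    expect_equal(fr2$transform$matrix %*% G$matrix, diag(4),
                 tolerance = 1e-9)
  }
  # the three defining landmarks lie on the returned reference plane
  expect_lt(abs(sum((c(55, 0, 0) - fr$plane$origin) * fr$plane$normal)), 1e-9)
  expect_error(build_articulator_frame(c(55, 0, 0), c(-55, 0, 0), c(0, 0, 0)),
               "degenerate-geometry")
  # swapped condyles flip the hinge axis and trip the orientation check
  expect_message(build_articulator_frame(c(-55, 0, 0), c(55, 0, 0),
                                         c(0, 80, 0)),
                 "orientation check")
})

test_that("frame construction is equivariant under pre-transformation", {
  set.seed(31)
  G <- random_rigid()
  cr <- c(52, 3, 1); cl <- c(-56, -1, 2); ap <- c(4, 78, 6)
  up <- c(0.1, -0.2, 1)
  base <- build_articulator_frame(cr, cl, ap, up_hint = up)
  moved <- build_articulator_frame(apply_transform(G, cr),
                                   apply_transform(G, cl),
                                   apply_transform(G, ap),
                                   up_hint = drop(G$matrix[1:3, 1:3] %*% up))
  expect_equal(moved$transform$matrix %*% G$matrix, base$transform$matrix,
               tolerance = 1e-9)
})

test_that("Kabsch alignment recovers known rigid transforms", {
  set.seed(3)
  src <- matrix(stats::rnorm(60, sd = 30), 20, 3)
  expect_equal(kabsch_align(src, src)$matrix, diag(4), tolerance = 1e-12)
  for (k in 1:10) {
    G <- random_rigid()
    est <- kabsch_align(src, apply_transform(G, src))
    expect_equal(est$matrix, G$matrix, tolerance = 1e-9)
  }
  # reflective correspondence still yields a proper rotation
  refl <- src %*% diag(c(-1, 1, 1))
  est <- kabsch_align(src, refl)
  expect_equal(det(est$matrix[1:3, 1:3]), 1, tolerance = 1e-9)
  rms <- sqrt(mean(rowSums((apply_transform(est, src) - refl)^2)))
  expect_gt(rms, 0)
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_align(line, line + 1), "degenerate-geometry")
})

test_that("ICP registers a perturbed cloud and reports honest quality", {
  pat <- generate_patient(4)
  sk <- sample_skin_clouds(pat, 200, noise_sigma = 0)
  same <- icp_register(sk$src, sk$src)
  expect_equal(same$transform$matrix, diag(4), tolerance = 1e-9)
  expect_lt(same$rms, 1e-9)
  # 5 deg / 2 mm perturbation from identity init
  G <- compose(make_translation(c(2, -1, 1)), make_rotation("y", 5 * pi / 180))
  reg <- icp_register(sk$src, apply_transform(G, sk$src))
  expect_lt(reg$rms, 1e-4)
  expect_equal(reg$transform$matrix, G$matrix, tolerance = 1e-6)
  # far-off init lands in a local minimum but reports its rms honestly
  far <- icp_register(sk$src, apply_transform(make_rotation("z", pi / 2), sk$src),
                      init = identity_transform(), max_iter = 10L)
  resid <- apply_transform(far$transform, sk$src)
  ref <- apply_transform(make_rotation("z", pi / 2), sk$src)
  nn <- apply(resid, 1, function(p) min(sqrt(colSums((t(ref) - p)^2))))
  expect_equal(far$rms, sqrt(mean(nn^2)), tolerance = 1e-6)
  expect_error(icp_register(sk$src[1:5, ], sk$src), "invalid-argument")
})

test_that("ICP rms is non-increasing across iterations (untrimmed)", {
  pat <- generate_patient(14)
  sk <- sample_skin_clouds(pat, 150, noise_sigma = 0.3)
  reg <- icp_register(sk$src, sk$dst, trim = 0)
  expect_true(all(diff(reg$rms_trace) <= 1e-9))
})

test_that("marker chain reproduces mandibular motion and cancels camera motion", {
  pat <- generate_patient(6)
  mov <- simulate_movement(pat, "protrusion", n_samples = 6, cycles = 1)
  em <- emit_marker_stream(pat, mov, camera_wobble = "none")
  # all-identity sanity: a co-moving pair leaves the point constant
  expect_equal(lower_point_in_articulator(c(1, 2, 3), 0,
                                          marker_pose_stream(0,
                                                             list(identity_transform()),
                                                             list(identity_transform())),
                                          identity_transform()),
               c(1, 2, 3))
  tr <- track_landmark_trajectory(em$marker_points$incisal, em$stream,
                                  em$T_0_up)
  expect_equal(tr$points, mov$clean$incisal$points, tolerance = 1e-9)
  # camera wobble cancels exactly
  em_w <- emit_marker_stream(pat, mov, camera_wobble = "random_walk")
  tr_w <- track_landmark_trajectory(em_w$marker_points$condyle_right,
                                    em_w$stream, em_w$T_0_up)
  tr_s <- track_landmark_trajectory(em$marker_points$condyle_right,
                                    em$stream, em$T_0_up)
  expect_equal(tr_w$points, tr_s$points, tolerance = 1e-9)
  expect_equal(tr_s$points, mov$clean$condyle_right$points, tolerance = 1e-9)
  expect_error(track_landmark_trajectory(c(0, 0, 0),
                                         marker_pose_stream(numeric(0), list(), list()),
                                         identity_transform()),
               "invalid-argument")
})
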