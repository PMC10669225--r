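# Rigid-transform algebra and the articulator joint chain.

test_that("elementary rotations and translations behave as a group", {
  expect_equal(apply_transform(make_rotation("z", pi / 2), c(1, 0, 0)),
               c(0, 1, 0), tolerance = 1e-12)
  expect_equal(make_rotation("x", 0)$matrix, diag(4))
  expect_equal(compose(make_rotation("y", 0.3), make_rotation("y", 0.9))$matrix,
               make_rotation("y", 1.2)$matrix, tolerance = 1e-12)
  expect_equal(make_translation(c(0, 0, 0))$matrix, diag(4))
  expect_equal(apply_transform(make_translation(c(1, 2, 3)), c(0, 0, 0)),
               c(1, 2, 3))
  expect_equal(compose(make_translation(c(4, -1, 2)),
                       make_translation(-c(4, -1, 2)))$matrix, diag(4))
  expect_error(make_rotation("z", Inf), "invalid-argument")
  expect_error(make_translation(c(1, NA, 0)), "invalid-argument")
})

test_that("compose/invert respect frame tags and rigid-group identities", {
  set.seed(41)
  for (k in 1:10) {
    A <- random_rigid(); B <- random_rigid(); C <- random_rigid()
    # chain equals direct matrix product; associativity
    expect_equal(compose(A, compose(B, C))$matrix, A$matrix %*% B$matrix %*% C$matrix,
                 tolerance = 1e-12)
    expect_equal(compose(compose(A, B), C)$matrix,
                 compose(A, compose(B, C))$matrix, tolerance = 1e-12)
    expect_equal(compose(A, invert(A))$matrix, diag(4), tolerance = 1e-12)
    expect_equal(invert(invert(A))$matrix, A$matrix, tolerance = 1e-12)
  }
  Tab <- framed_transform(diag(4), from = "a", to = "b")
  Tbc <- framed_transform(diag(4), from = "b", to = "c")
  out <- compose(Tbc, Tab)
  expect_identical(c(out$from, out$to), c("a", "c"))
  expect_identical(c(invert(Tab)$from, invert(Tab)$to), c("b", "a"))
  expect_error(compose(Tab, Tbc), "frame-mismatch")
  # inverse of a pure translation
  expect_equal(invert(make_translation(c(1, 2, 3)))$matrix,
               make_translation(c(-1, -2, -3))$matrix)
})

test_that("transform invariants reject non-rigid matrices", {
  m <- diag(4); m[1, 1] <- 2
  expect_error(framed_transform(m), "orthonormal")
  m <- diag(4); m[4, 1] <- 1
  expect_error(framed_transform(m), "last row")
  m <- diag(c(-1, 1, 1, 1))
  expect_error(framed_transform(m), "determinant")
})

test_that("transform JSON serialization round-trips", {
  T <- random_rigid()
  T$from <- "ct"; T$to <- "articulator"
  path <- withr::local_tempfile(fileext = ".json")
  write_transform_json(T, path)
  T2 <- read_transform_json(path)
  expect_equal(T2$matrix, T$matrix, tolerance = 1e-12)
  expect_identical(c(T2$from, T2$to), c("ct", "articulator"))
})

test_that("articulator joint chain composes translation and rotations", {
  p0 <- articulator_parameters()
  ch0 <- articulator_joint_chain(p0, "right")
  expect_equal(ch0$T01$matrix, diag(4))
  expect_equal(ch0$T12$matrix, diag(4))
  # condylar inclination adjuster alone rotates about x
  a <- 0.4
  ch <- articulator_joint_chain(articulator_parameters(theta2 = a), "right")
  expect_equal(apply_transform(ch$T12, c(0, 1, 0)),
               c(0, cos(a), sin(a)), tolerance = 1e-12)
  # explicit matrix product oracle for a full chain
  p <- articulator_parameters(theta_sag = 0.5, theta1 = 0.2, theta2 = 0.35,
                              p01 = c(55, 0, 0), p12 = c(1, -2, 3))
  ch <- articulator_joint_chain(p, "right")
  M <- make_translation(c(55, 0, 0))$matrix %*% make_rotation("x", 0.5)$matrix %*%
    make_rotation("z", 0.2)$matrix
  expect_equal(ch$T01$matrix, M, tolerance = 1e-12)
  pt <- c(2, 5, -1)
  expect_equal(map_joint2_point_to_world(pt, ch$T01, ch$T12),
               drop((ch$T01$matrix %*% ch$T12$matrix %*% c(pt, 1))[1:3]),
               tolerance = 1e-12)
})

test_that("left chain is the sagittal mirror of the right chain", {
  p <- articulator_parameters(theta_sag = 0.5, theta1 = 0.2, theta2 = 0.35,
                              p01 = c(55, 0, 0), p12 = c(1, -2, 3))
  chR <- articulator_joint_chain(p, "right")
  chL <- articulator_joint_chain(p, "left")
  set.seed(7)
  for (k in 1:5) {
    pt <- stats::rnorm(3)
    wR <- map_joint2_point_to_world(pt, chR$T01, chR$T12)
    wL <- map_joint2_point_to_world(pt * c(-1, 1, 1), chL$T01, chL$T12)
    expect_equal(wL, wR * c(-1, 1, 1), tolerance = 1e-12)
  }
})

test_that("world_to_condyle_frame is the condyle-centering translation", {
  lm <- anatomical_landmarks(c(55, 0, 0), c(-55, 0, 0), c(0, 80, 0),
                             c(0, 95, -40))
  T0R <- world_to_condyle_frame(lm, "right")
  expect_equal(apply_transform(T0R, c(55, 0, 0)), c(0, 0, 0))
  # translation preserves displacement vectors and round-trips
  P <- c(1, 2, 3); Q <- c(-4, 0, 9)
  expect_equal(apply_transform(T0R, P) - apply_transform(T0R, Q), P - Q)
  expect_equal(apply_transform(invert(T0R), apply_transform(T0R, P)), P)
  lm_ct <- lm; lm_ct$frame <- "ct"
  expect_error(world_to_condyle_frame(lm_ct, "right"), "frame-mismatch")
})

test_that("apply_jaw_pose is the conjugated rigid displacement about the condyle", {
  c0 <- c(55, 0, 0)
  expect_equal(apply_jaw_pose(jaw_pose(), c0, c(0, 95, -40)), c(0, 95, -40))
  expect_equal(apply_jaw_pose(jaw_pose(t_x = 1, t_y = -2, t_z = 3), c0,
                              c(0, 95, -40)),
               c(1, 93, -37))
  # explicit matrix oracle: rotation 90 deg about z at the condyle
  p <- c(10, 20, -5)
  got <- apply_jaw_pose(jaw_pose(theta_z = pi / 2, t_x = 1), c0, p)
  rel <- p - c0
  expect_equal(got, c0 + c(-rel[2], rel[1], rel[3]) + c(1, 0, 0),
               tolerance = 1e-12)
  expect_error(jaw_pose(theta_x = NaN), "invalid-argument")
})

test_that("jaw poses are rigid: pairwise distances are preserved", {
  set.seed(11)
  pts <- matrix(stats::rnorm(30, sd = 30), 10, 3)
  pose <- jaw_pose(0.2, -0.1, 0.3, 4, -2, 1)
  moved <- apply_jaw_pose(pose, c(55, 0, 0), pts)
  expect_equal(as.vector(stats::dist(moved)), as.vector(stats::dist(pts)),
               tolerance = 1e-9)
})

test_that("landmark and parameter invariants are enforced", {
  expect_error(anatomical_landmarks(c(0, 0, 0), c(0.5, 0, 0), c(0, 80, 0),
                                    c(0, 95, -40)),
               "degenerate-geometry")
  expect_error(anatomical_landmarks(c(55, 0, 0), c(-55, 0, 0), c(0, 0.001, 0),
                                    c(0, 95, -40)),
               "degenerate-geometry")
  expect_error(articulator_parameters(intercondylar_width = -1),
               "invalid-argument")
  expect_error(articulator_parameters(theta1 = 2), "invalid-argument")
})
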