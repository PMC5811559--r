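test_that("world_to_camera applies the rigid transform and inverts", {
  cam <- camera_model(R = diag(3), t = c(0, 0, 0), f = 1, u0 = 0, v0 = 0)
  expect_equal(world_to_camera(cam, c(1, 2, 3)), c(1, 2, 3))

  Rz180 <- rotation_about_axis(c(0, 0, 1), 180)
  cam2 <- camera_model(R = Rz180, t = c(0, 0, 0), f = 1, u0 = 0, v0 = 0)
  expect_equal(world_to_camera(cam2, c(1, 0, 0)), c(-1, 0, 0),
               tolerance = 1e-12)

  set.seed(7)
  for (i in 1:10) {
    R <- random_rotation()
    t <- stats::rnorm(3)
    cam3 <- camera_model(R = R, t = t, f = 100, u0 = 50, v0 = 50)
    p <- matrix(stats::rnorm(30), 10, 3)
    # oracle: explicit 4x4 homogeneous multiply
    M4 <- rbind(cbind(R, t), c(0, 0, 0, 1))
    oracle <- t(M4 %*% rbind(t(p), 1))[, 1:3]
    expect_equal(world_to_camera(cam3, p), oracle, tolerance = 1e-12)
    expect_equal(camera_to_world(cam3, world_to_camera(cam3, p)), p,
                 tolerance = 1e-12)
  }
})

test_that("project_point implements the perspective + distortion model", {
  cam <- camera_model(R = diag(3), t = c(0, 0, 0), f = 100, s = 1,
                      u0 = 50, v0 = 50)
  # optical axis maps to the principal point at any distance
  expect_equal(project_point(cam, c(0, 0, 1)), c(u = 50, v = 50))
  expect_equal(project_point(cam, c(0, 0, 77)), c(u = 50, v = 50))
  # worked example: camera-frame point (1, 0, 2) with f = 100
  expect_equal(project_point(cam, c(1, 0, 2)), c(u = 100, v = 50))

  # k1 != 0 against a step-by-step scalar oracle
  cam_d <- camera_model(R = diag(3), t = c(0.1, -0.2, 0.3), f = 120,
                        s = 1.1, u0 = 40, v0 = 60, k1 = -0.05)
  set.seed(11)
  for (i in 1:20) {
    p <- c(stats::rnorm(2, sd = 0.5), stats::runif(1, 1, 5))
    pc <- drop(cam_d$R %*% p + cam_d$t)
    x <- pc[1] / pc[3]; y <- pc[2] / pc[3]
    r2 <- x^2 + y^2
    xd <- x * (1 + cam_d$k1 * r2); yd <- y * (1 + cam_d$k1 * r2)
    oracle <- c(cam_d$f * xd + cam_d$u0, cam_d$s * cam_d$f * yd + cam_d$v0)
    expect_equal(unname(project_point(cam_d, p)), oracle, tolerance = 1e-12)
  }
})

test_that("projection errors on points at or behind the camera plane", {
  cam <- camera_model(R = diag(3), t = c(0, 0, 0), f = 100, u0 = 0, v0 = 0)
  expect_error(project_point(cam, c(0, 0, -1)), "unprojectable")
  expect_error(project_point(cam, c(1, 1, 0)), "unprojectable")
  uv <- project_point(cam, rbind(c(0, 0, -1), c(0, 0, 2)),
                      allow_behind = TRUE)
  expect_true(all(is.na(uv[1, ])))
  expect_false(anyNA(uv[2, ]))
})

test_that("undistorted projection equals the single-matrix formulation", {
  set.seed(3)
  cam <- camera_model(R = random_rotation(), t = c(0.3, -0.1, 0.2),
                      f = 300, s = 1.05, u0 = 120, v0 = 110)
  P <- projection_matrix(cam)
  pts <- matrix(stats::rnorm(3000), 1000, 3)
  # keep only points in front of the camera
  z <- world_to_camera(cam, pts)[, 3]
  pts <- pts[z > 0.1, , drop = FALSE]
  h <- t(P %*% rbind(t(pts), 1))
  oracle <- h[, 1:2] / h[, 3]
  got <- project_point(cam, pts)
  expect_equal(unname(got), unname(oracle), tolerance = 1e-9)
})

test_that("camera normal points from the camera toward its target", {
  cam <- fx_camera()
  nic <- camera_normal(cam)
  expect_equal(sqrt(sum(nic^2)), 1, tolerance = 1e-12)
  to_origin <- -camera_position(cam)
  expect_gt(sum(nic * to_origin), 0)
})

test_that("pose adjustments compose and invert", {
  cam <- fx_camera()
  same <- adjust_camera_pose(cam)
  expect_equal(same$R, cam$R, tolerance = 1e-15)
  expect_equal(same$t, cam$t, tolerance = 1e-15)

  fwd <- adjust_camera_pose(cam, delta_rotation = c(0, 1, 0))
  back <- adjust_camera_pose(fwd, delta_rotation = c(0, -1, 0))
  expect_equal(back$R, cam$R, tolerance = 1e-12)
  expect_equal(back$t, cam$t, tolerance = 1e-12)

  # correcting a perturbed camera by the negative deltas restores the
  # reprojection quality
  cuboid <- calibration_cuboid()
  XYZ <- cuboid_junctions(cuboid)
  labels <- seq_len(nrow(XYZ))
  obs <- junction_observations(project_point(cam, XYZ), labels)
  pert <- adjust_camera_pose(cam, delta_rotation = c(0.5, 0, 0),
                             delta_translation = c(0.02, 0, 0))
  fixed <- adjust_camera_pose(pert, delta_rotation = c(-0.5, 0, 0),
                              delta_translation = c(-0.02, 0, 0))
  expect_gt(reprojection_rmse(pert, obs, cuboid), 0.5)
  expect_lt(reprojection_rmse(fixed, obs, cuboid),
            reprojection_rmse(pert, obs, cuboid) / 10)
  # a pure-rotation perturbation undoes exactly
  pert_r <- adjust_camera_pose(cam, delta_rotation = c(0, 0.4, 0))
  fixed_r <- adjust_camera_pose(pert_r, delta_rotation = c(0, -0.4, 0))
  expect_lt(reprojection_rmse(fixed_r, obs, cuboid), 1e-9)
})

test_that("camera model validates its invariants", {
  expect_error(camera_model(R = matrix(1, 3, 3), t = rep(0, 3), f = 1,
                            u0 = 0, v0 = 0), "orthonormal")
  flipped <- diag(c(1, 1, -1))
  expect_error(camera_model(R = flipped, t = rep(0, 3), f = 1,
                            u0 = 0, v0 = 0), "det")
  expect_error(camera_model(R = diag(3), t = rep(0, 3), f = -1,
                            u0 = 0, v0 = 0))
})
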