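# brute-force oracle: classify every finest-grid cell by its 8 corners
brute_force_carve <- function(stack, bounds, depth) {
  nf <- 2^depth
  h <- bounds$extent / nf
  # corner lattice inside-tests
  cg <- expand.grid(i = 0:nf, j = 0:nf, k = 0:nf)
  pts <- cbind(bounds$origin[1] + cg$i * h[1],
               bounds$origin[2] + cg$j * h[2],
               bounds$origin[3] + cg$k * h[3])
  ins <- array(points_in_hull(pts, stack), dim = c(nf + 1, nf + 1, nf + 1))
  occ <- array(0, c(nf, nf, nf))
  cnt <- array(0L, c(nf, nf, nf))
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1)
    cnt <- cnt + ins[(1:nf) + di, (1:nf) + dj, (1:nf) + dk]
  occ[cnt == 8] <- 1
  occ[cnt > 0 & cnt < 8] <- 0.5
  occ
}

small_stack <- function(n_views = 3, size = 64) {
  geo <- look_at_camera(c(6, 0, 0), f = size * 1.2, u0 = (size - 1) / 2,
                        v0 = (size - 1) / 2, image_size = c(size, size))
  solid <- analytic_solid("ellipsoid", semi_axes = c(0.7, 0.5, 0.9))
  stack <- render_rotation_silhouettes(
    solid, geo, angles = seq(0, by = 40, length.out = n_views))
  list(stack = stack, solid = solid)
}

test_that("voxel classification follows the all-corner rule", {
  fs <- fx_sphere_stack()
  cube_corners <- function(center, half) {
    offs <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) * half
    sweep(offs, 2, center, `+`)
  }
  expect_equal(classify_voxel(cube_corners(c(3, 3, 3), 0.1), fs$stack),
               "outside")
  expect_equal(classify_voxel(cube_corners(c(0, 0, 0), 0.05), fs$stack),
               "inside")
  # voxel straddling the sphere boundary; analytic corner test agrees
  corners <- cube_corners(c(0.8, 0, 0), 0.1)
  ana <- solid_inside(fs$solid, corners)
  expect_true(any(ana) && !all(ana))
  expect_equal(classify_voxel(corners, fs$stack), "boundary")
})

test_that("octree carving equals brute-force dense-grid carving", {
  ss <- small_stack()
  bounds <- list(origin = rep(-1, 3), extent = rep(2, 3))
  for (depth in c(3, 5)) {
    oct <- carve_visual_hull(ss$stack, bounds, max_depth = depth)
    bf <- brute_force_carve(ss$stack, bounds, depth)
    expect_identical(oct$occupancy, bf)
  }
})

test_that("a carved axis-aligned cube matches its analytic volume", {
  size <- 80
  geo <- look_at_camera(c(6, 0, 0), f = 110, u0 = (size - 1) / 2,
                        v0 = (size - 1) / 2, image_size = c(size, size))
  solid <- analytic_solid("cuboid", dims = c(1, 1, 1))
  stack <- render_rotation_silhouettes(solid, geo, seq(0, 355, by = 5))
  vol <- carve_visual_hull(stack,
                           bounds = list(origin = rep(-0.75, 3),
                                         extent = rep(1.5, 3)),
                           max_depth = 5)
  # hull volume within one finest-voxel surface shell of the cube
  h <- vol$resolution
  v_in <- (1 - 2 * h)^3
  v_out <- (1 + 2 * h)^3
  expect_gte(carved_volume(vol), v_in)
  expect_lte(carved_volume(vol), v_out)
})

test_that("72-view carving reproduces the sphere volume", {
  fx <- fx_sphere_mesh()
  r <- fx$solid$radius
  expect_lt(abs(carved_volume(fx$volume) - 4 / 3 * pi * r^3) /
              (4 / 3 * pi * r^3), 0.05)
})

test_that("the hull is conservative: the true solid is inside it", {
  fx <- fx_sphere_mesh()
  vol <- fx$volume
  nf <- dim(vol$occupancy)[1]
  h <- vol$extent / nf
  set.seed(9)
  pts <- matrix(stats::runif(3000, -1, 1), ncol = 3) * fx$solid$radius
  pts <- pts[solid_inside(fx$solid, pts), , drop = FALSE]
  idx <- floor(sweep(pts, 2, vol$origin) / matrix(h, nrow(pts), 3,
                                                  byrow = TRUE)) + 1
  ok <- idx >= 1 & idx <= nf
  idx <- idx[rowSums(ok) == 3, , drop = FALSE]
  expect_true(all(vol$occupancy[idx] >= 0.5))
})

test_that("carved volume is non-increasing as silhouettes are added", {
  ss <- small_stack(n_views = 6)
  bounds <- list(origin = rep(-1.1, 3), extent = rep(2.2, 3))
  vols <- vapply(c(2, 4, 6), function(nv) {
    sub <- assemble_stack(ss$stack$masks[1:nv], camera = ss$stack$camera,
                          angles = ss$stack$angles[1:nv])
    carved_volume(carve_visual_hull(sub, bounds, max_depth = 4))
  }, numeric(1))
  expect_true(all(diff(vols) <= 1e-12))
})

test_that("degenerate stacks are rejected", {
  ss <- small_stack()
  empty <- ss$stack
  empty$masks[[2]] <- empty$masks[[2]] * 0
  expect_error(carve_visual_hull(empty, max_depth = 3),
               "degenerate silhouette")
})
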