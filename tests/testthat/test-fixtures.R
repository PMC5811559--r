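test_that("the rendered target's ground truth is self-consistent", {
  fx <- fx_target()
  truth <- fx$rend$truth
  expect_equal(nrow(truth$pixels), 64)
  # ground truth reproduced by project_point exactly
  uv <- project_point(fx$camera, cuboid_junctions(fx$cuboid, truth$labels))
  expect_equal(unname(truth$pixels), unname(uv), tolerance = 1e-12)
  # the detector recovers >= 95% of them within half a pixel
  pts <- detect_junctions(fx$rend$image, fx$rend$mask)
  d <- sqrt(outer(pts[, 1], truth$pixels[, 1], "-")^2 +
              outer(pts[, 2], truth$pixels[, 2], "-")^2)
  expect_gte(mean(apply(d, 2, min) < 0.5), 0.95)
})

test_that("silhouette renders obey the solids' symmetries", {
  geo <- look_at_camera(c(6, 0, 0), f = 150, u0 = 39.5, v0 = 39.5,
                        image_size = c(80, 80))
  sph <- analytic_solid("sphere", radius = 0.8)
  st <- render_rotation_silhouettes(sph, geo, angles = seq(0, 300, by = 60))
  for (i in 2:length(st$masks))
    expect_identical(st$masks[[i]], st$masks[[1]])

  # off-axis sphere: mask centroid in u traces a sinusoid over angle
  off <- analytic_solid("sphere", center = c(0.45, 0, 0), radius = 0.35)
  angles <- seq(0, 350, by = 10)
  st2 <- render_rotation_silhouettes(off, geo, angles = angles)
  cen_u <- vapply(st2$masks, function(m) {
    idx <- which(m == 1, arr.ind = TRUE)
    mean(idx[, 2] - 1)
  }, numeric(1))
  fit <- stats::lm(cen_u ~ cos(angles * pi / 180) + sin(angles * pi / 180))
  expect_gt(summary(fit)$r.squared, 0.995)   # rasterized at ~9 px radius

  # cuboid silhouette area has 90-degree periodicity
  cub <- analytic_solid("cuboid", dims = c(0.8, 0.8, 1.2))
  st3 <- render_rotation_silhouettes(cub, geo, angles = seq(0, 350, by = 10))
  areas <- vapply(st3$masks, sum, numeric(1))
  expect_lt(max(abs(areas[1:9] - areas[10:18])) / mean(areas), 0.01)

  # solid out of view errors
  far <- analytic_solid("sphere", center = c(0, 0, 50), radius = 0.2)
  expect_error(render_rotation_silhouettes(far, geo, angles = 0),
               "out of frame")
})

test_that("synthetic action potentials are deterministic with exact APD", {
  tpl <- ap_template(upstroke_time = 25, upstroke_duration = 0,
                     plateau_duration = 0, repolarization_duration = 100)
  tr <- synth_action_potential(tpl, 200, 1000)
  act <- activation_times(rbind(tr), 1000)
  apd <- apd_map(rbind(tr), act, 1000, level = 0.8)
  expect_equal(analytic_apd(tpl, 0.8), 80)
  expect_lte(abs(apd$values[1] - 80), 0.5)

  a <- synth_action_potential(tpl, 200, 1000, noise_sd = 0.02, seed = 99)
  b <- synth_action_potential(tpl, 200, 1000, noise_sd = 0.02, seed = 99)
  expect_identical(a, b)
  cc <- synth_action_potential(tpl, 200, 1000, noise_sd = 0.02, seed = 100)
  expect_false(identical(a, cc))

  # noisy APD recovery over many seeds
  tpl2 <- ap_template(upstroke_time = 20, upstroke_duration = 2,
                      plateau_duration = 30, repolarization_duration = 100)
  errs <- vapply(1:100, function(sd_) {
    tr <- synth_action_potential(tpl2, 250, 1000, noise_sd = 0.02,
                                 seed = sd_)
    sm <- stats::filter(tr, rep(1 / 5, 5), sides = 2)
    sm[is.na(sm)] <- tr[is.na(sm)]
    act <- activation_times(rbind(as.numeric(sm)), 1000)
    apd_map(rbind(as.numeric(sm)), act, 1000, 0.8)$values[1] -
      analytic_apd(tpl2, 0.8)
  }, numeric(1))
  expect_lt(mean(abs(errs)), 2)
})

test_that("plane-wave movies encode activation linear in the coordinate", {
  cams <- default_camera_ring(n = 2, image_size = c(60, 60), f = 240)
  solid <- analytic_solid("sphere", radius = 0.8)
  pat <- activation_pattern("plane_wave", direction = c(0, 0, 1),
                            speed = 0.04, t0 = 5)
  ico <- icosphere(2, radius = 0.8)
  syn <- synth_camera_movies(solid, pat, cams, duration_ms = 100,
                             sampling_rate = 500, mesh = ico)
  gt <- syn$ground_truth$activation
  z <- ico$face_centroids[, 3]
  fit <- stats::lm(gt ~ z)
  expect_equal(unname(stats::coef(fit)[2]), 1 / 0.04, tolerance = 1e-9)
  # earliest activation just above t0 (+ half upstroke); the margin is
  # the centroid inset of the coarse sphere mesh divided by the speed
  t_first <- 5 + syn$ground_truth$template$upstroke_duration / 2
  expect_gte(min(gt), t_first)
  expect_lt(min(gt), t_first + 1)

  # per-camera movies are seed-deterministic
  s1 <- synth_camera_movies(solid, pat, cams, duration_ms = 40,
                            sampling_rate = 500, noise_sd = 0.01, seed = 3)
  s2 <- synth_camera_movies(solid, pat, cams, duration_ms = 40,
                            sampling_rate = 500, noise_sd = 0.01, seed = 3)
  expect_identical(s1$movies$A$frames, s2$movies$A$frames)
})

test_that("spiral-pattern movies wind once around the core", {
  cams <- default_camera_ring(n = 4, image_size = c(60, 60), f = 240)
  solid <- analytic_solid("sphere", radius = 0.8)
  pat <- activation_pattern("spiral", frequency = 8, chirality = 1,
                            core_lonlat = c(20.25, 10.25))
  ico <- icosphere(3, radius = 0.8)
  syn <- synth_camera_movies(solid, pat, cams, duration_ms = 500,
                             sampling_rate = 500, mesh = ico)
  # ground-truth per-face signals -> phase -> unwrapped raster -> PS
  ph <- compute_phase(syn$ground_truth$signals, 500)
  par <- spherical_parameterize(ico)
  frame <- 150
  ras <- project_mercator(par, ph$phase[, frame], resolution = 72,
                          max_lat = 60)
  ps <- detect_phase_singularities(ras$grid, tol = pi / 2)
  expect_gte(nrow(ps), 1)
  # the dominant singularity sits near the core longitude/latitude
  lon_ps <- ras$lon_grid[round(ps$u + 0.5)]
  expect_lt(min(abs(lon_ps - 20.25)), 15)
})
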