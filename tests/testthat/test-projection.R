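test_that("face classification honors the 90 / 115 degree thresholds", {
  cam <- fx_camera()
  expect_equal(classify_faces(tri_at_angle(180, cam), cam), "assigned")
  expect_equal(classify_faces(tri_at_angle(89, cam), cam), "excluded")
  expect_equal(classify_faces(tri_at_angle(100, cam), cam), "edge")
  # boundary angles are edge (closed interval)
  expect_equal(classify_faces(tri_at_angle(90, cam), cam), "edge")
  expect_equal(classify_faces(tri_at_angle(115, cam), cam), "edge")
  expect_equal(classify_faces(tri_at_angle(116, cam), cam), "assigned")
  expect_equal(classify_faces(tri_at_angle(0, cam), cam), "excluded")
})

test_that("classification partitions every face for each camera", {
  cams <- default_camera_ring()
  ico <- icosphere(2, radius = 0.8)
  for (cam in cams) {
    kl <- classify_faces(ico, cam)
    expect_true(all(kl %in% c("excluded", "edge", "assigned")))
    expect_equal(length(kl), nrow(ico$faces))
  }
  # panoramic coverage: four cameras at 90 degrees leave almost nothing
  # excluded everywhere on a sphere
  kl4 <- vapply(cams, function(cam) classify_faces(ico, cam),
                character(nrow(ico$faces)))
  non_excl <- rowSums(kl4 != "excluded") > 0
  expect_gte(mean(non_excl), 0.99)
})

test_that("centroid projection lands on analytic pixel positions", {
  cam <- fx_camera(size = 101)   # integer principal point
  # centroid on the optical axis
  pos <- camera_position(cam)
  nic <- camera_normal(cam)
  p <- pos + 2 * nic
  tri <- surface_mesh(rbind(p + c(0.01, 0, 0), p + c(0, 0.01, 0),
                            p - c(0.01, 0.01, 0) / 3), rbind(1:3))
  tri$face_centroids <- matrix(p, 1)   # exact axis point
  px <- project_centroids(tri, cam)
  expect_equal(unname(px[1, ]), round(c(cam$u0, cam$v0)))

  # behind the camera -> invalid
  tri_b <- tri
  tri_b$face_centroids <- matrix(pos - 2 * nic, 1)
  expect_true(all(is.na(project_centroids(tri_b, cam))))

  # outside the frustum -> invalid
  tri_o <- tri
  tri_o$face_centroids <- matrix(pos + 2 * nic + 5, 1)
  expect_true(all(is.na(project_centroids(tri_o, cam))))

  # sphere centroids agree with direct projection within rounding
  ico <- icosphere(2, radius = 0.5)
  px2 <- project_centroids(ico, cam)
  uv <- project_point(cam, ico$face_centroids)
  ok <- !is.na(px2[, 1])
  expect_true(all(abs(px2[ok, ] - uv[ok, ]) <= 0.5 + 1e-12))
})

test_that("overlap blending follows the weighted-average formula", {
  # two cameras staring at one triangle from opposite sides of its normal
  camA <- fx_camera(az_deg = 0, dist = 5, height = 0, f = 100, size = 50)
  camB <- fx_camera(az_deg = 40, dist = 5, height = 0, f = 100, size = 50)
  tri <- tri_at_angle(180, camA)   # faces camera A squarely; B at 140
  Tn <- 10
  mkmovie <- function(val, id) {
    fr <- array(val, c(50, 50, Tn))
    optical_movie(fr, 1000, camera_id = id)
  }
  movies <- list(A = mkmovie(2, "A"), B = mkmovie(0, "B"))
  wA <- build_weight_mask(matrix(1, 50, 50))
  # force the weights: uniform masks give weight 1 everywhere; scale B
  wB <- wA
  wB$weights <- wA$weights * 0.5
  ds <- assemble_projected_signals(tri, movies,
                                   list(A = wA, B = wB),
                                   list(A = camA, B = camB))
  expect_equal(ds$class, "overlap")
  expect_equal(unname(ds$signals[1, ]), rep((1 * 2 + 0.5 * 0) / 1.5, Tn))
})

test_that("faces seen by one camera copy that camera's closest pixel", {
  cams <- default_camera_ring(image_size = c(60, 60), f = 240, distance = 10)
  solid <- analytic_solid("sphere", radius = 0.8)
  pat <- activation_pattern("plane_wave", direction = c(0, 0, 1),
                            speed = 0.02)
  ico <- icosphere(3, radius = 0.8)
  syn <- synth_camera_movies(solid, pat, cams, duration_ms = 120,
                             sampling_rate = 500, mesh = ico)
  wm <- lapply(syn$movies, function(m) build_weight_mask(m$mask))
  ds <- assemble_projected_signals(ico, syn$movies, wm, cams)
  one_cam <- which(ds$class == "assigned")
  expect_gt(length(one_cam), 0)
  i <- one_cam[1]
  a <- ds$assignments[[i]]
  expect_equal(length(a$cameras), 1)
  id <- a$cameras[[1]]$camera_id
  px <- a$cameras[[1]]$pixel
  mv <- syn$movies[[id]]
  expect_equal(unname(ds$signals[i, ]),
               unname(mv$frames[px[2] + 1, px[1] + 1, ]))

  # blended traces are convex combinations: within per-face camera bounds
  expect_true(all(ds$signals[!is.na(ds$signals[, 1]), ] >= 0 - 1e-12))
  expect_true(all(ds$signals[!is.na(ds$signals[, 1]), ] <= 1 + 1e-12))

  # excluded faces carry missing signal
  expect_true(all(is.na(ds$signals[ds$class == "excluded", ])))

  # movies of different lengths are rejected
  short <- syn$movies
  short$A$frames <- short$A$frames[, , 1:10]
  expect_error(assemble_projected_signals(ico, short, wm, cams),
               "length mismatch")
})
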