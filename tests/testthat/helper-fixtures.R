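# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# a well-posed camera looking at the origin from a corner-on azimuth
fx_camera <- function(az_deg = 45, dist = 8, height = 1, f = 600,
                      size = 480) {
  az <- az_deg * pi / 180
  look_at_camera(c(dist * cos(az), dist * sin(az), height),
                 f = f, u0 = (size - 1) / 2, v0 = (size - 1) / 2,
                 image_size = c(size, size))
}

# rendered calibration target with ground truth (heavier; cached)
fx_target <- function() {
  fixture("target", function() {
    cuboid <- calibration_cuboid()
    camera <- fx_camera()
    rend <- render_calibration_target(camera, cuboid)
    list(cuboid = cuboid, camera = camera, rend = rend)
  })
}

# small geometry camera + sphere silhouette stack for carving tests
fx_sphere_stack <- function() {
  fixture("sphere_stack", function() {
    geo <- look_at_camera(c(8, 0, 0), f = 300, u0 = 79.5, v0 = 79.5,
                          image_size = c(160, 160))
    solid <- analytic_solid("sphere", radius = 0.8)
    stack <- render_rotation_silhouettes(solid, geo,
                                         angles = seq(0, 355, by = 5))
    list(geo = geo, solid = solid, stack = stack)
  })
}

# carved sphere volume and mesh at moderate depth (cached; used by
# several mesh tests)
fx_sphere_mesh <- function() {
  fixture("sphere_mesh", function() {
    fs <- fx_sphere_stack()
    volume <- carve_visual_hull(fs$stack, max_depth = 5)
    mesh <- extract_surface(volume)
    list(volume = volume, mesh = mesh, solid = fs$solid)
  })
}

# random proper rotation matrix
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; cc <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - cc^2 - d^2, 2 * (b * cc + a * d), 2 * (b * d - a * cc),
           2 * (b * cc - a * d), a^2 - b^2 + cc^2 - d^2, 2 * (cc * d + a * b),
           2 * (b * d + a * cc), 2 * (cc * d - a * b), a^2 - b^2 - cc^2 + d^2),
         3, 3)
}

# a single-triangle mesh whose normal makes a given angle with the
# viewing direction of `camera`
tri_at_angle <- function(theta_deg, camera, center = c(0, 0, 0)) {
  nic <- camera_normal(camera)
  # rotate nic by theta about an axis orthogonal to it
  ref <- if (abs(nic[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  ax <- c(nic[2] * ref[3] - nic[3] * ref[2],
          nic[3] * ref[1] - nic[1] * ref[3],
          nic[1] * ref[2] - nic[2] * ref[1])
  n <- drop(rotation_about_axis(ax, theta_deg) %*% nic)
  # build a triangle with normal n (winding fixed to match)
  e1 <- ref - sum(ref * n) * n; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  v <- rbind(center + 0.1 * e1, center + 0.1 * e2,
             center - 0.1 * (e1 + e2))
  m <- surface_mesh(v, rbind(c(1, 2, 3)))
  if (sum(m$face_normals * n) < 0)
    m <- surface_mesh(v, rbind(c(1, 3, 2)))
  m
}

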