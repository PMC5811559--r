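#' Analytic test solid
#'
#' Exact stand-in for the heart: a solid with closed-form inside tests
#' and ray intersections, so silhouettes and carved volumes can be
#' checked against analytic ground truth.
#'
#' @param kind `"sphere"`, `"ellipsoid"` or `"cuboid"`.
#' @param center 3-vector, world units.
#' @param radius sphere radius.
#' @param semi_axes ellipsoid semi-axes (3-vector).
#' @param dims cuboid edge lengths (3-vector).
#' @return An object of class `analytic_solid` (all kinds are convex).
#' @export
analytic_solid <- function(kind = c("sphere", "ellipsoid", "cuboid"),
                           center = c(0, 0, 0), radius = 1,
                           semi_axes = c(1, 1, 1), dims = c(1, 1, 1)) {
  kind <- match.arg(kind)
  structure(list(kind = kind, center = as.numeric(center),
                 radius = radius, semi_axes = as.numeric(semi_axes),
                 dims = as.numeric(dims), convex = TRUE),
            class = "analytic_solid")
}

#' Support extent of a solid along a direction
#'
#' Half-width of the solid from its center along a unit direction
#' (support function of the centered solid); all kinds are symmetric.
#' @param solid an [analytic_solid()].
#' @param direction unit 3-vector.
#' @export
solid_support <- function(solid, direction) {
  d <- direction / sqrt(sum(direction^2))
  switch(solid$kind,
         sphere = solid$radius,
         ellipsoid = sqrt(sum((solid$semi_axes * d)^2)),
         cuboid = sum(solid$dims / 2 * abs(d)))
}

#' Exact inside test for an analytic solid
#' @param solid an [analytic_solid()].
#' @param points N x 3 matrix or 3-vector.
#' @return Logical vector.
#' @export
solid_inside <- function(solid, points) {
  p <- sweep(as_point_matrix(points), 2, solid$center)
  switch(solid$kind,
         sphere = rowSums(p^2) <= solid$radius^2,
         ellipsoid = rowSums(sweep(p, 2, solid$semi_axes, `/`)^2) <= 1,
         cuboid = apply(abs(p) <= matrix(solid$dims / 2, nrow(p), 3,
                                         byrow = TRUE), 1, all))
}

# do rays (origins O, unit directions D; N x 3 each) hit the solid?
# returns list(hit, tmin) with tmin the first positive hit parameter
.ray_solid_hit <- function(solid, O, D) {
  O <- sweep(O, 2, solid$center)
  if (solid$kind == "ellipsoid") {
    O <- sweep(O, 2, solid$semi_axes, `/`)
    D <- sweep(D, 2, solid$semi_axes, `/`)
    r2 <- 1
  } else if (solid$kind == "sphere") {
    r2 <- solid$radius^2
  }
  if (solid$kind %in% c("sphere", "ellipsoid")) {
    a <- rowSums(D^2)
    b <- 2 * rowSums(O * D)
    cc <- rowSums(O^2) - r2
    disc <- b^2 - 4 * a * cc
    hit <- disc >= 0
    t1 <- (-b - sqrt(pmax(disc, 0))) / (2 * a)
    t2 <- (-b + sqrt(pmax(disc, 0))) / (2 * a)
    tmin <- ifelse(t1 > 0, t1, t2)
    hit <- hit & tmin > 0
    return(list(hit = hit, tmin = tmin))
  }
  # cuboid: slab method
  half <- solid$dims / 2
  t0 <- rep(-Inf, nrow(O)); t1v <- rep(Inf, nrow(O))
  ok <- rep(TRUE, nrow(O))
  for (ax in 1:3) {
    d <- D[, ax]; o <- O[, ax]
    par <- abs(d) < 1e-14
    ok <- ok & (!par | abs(o) <= half[ax])
    ta <- (-half[ax] - o) / d
    tb <- (half[ax] - o) / d
    lo <- pmin(ta, tb); hi <- pmax(ta, tb)
    t0 <- ifelse(par, t0, pmax(t0, lo))
    t1v <- ifelse(par, t1v, pmin(t1v, hi))
  }
  hit <- ok & t0 <= t1v & t1v > 0
  list(hit = hit, tmin = ifelse(t0 > 0, t0, t1v))
}

# pixel-center rays of a camera in the world frame (k1 ignored)
.pixel_rays <- function(camera) {
  W <- camera$image_size[1]; H <- camera$image_size[2]
  u <- rep(0:(W - 1), each = H)
  v <- rep(0:(H - 1), times = W)
  x <- (u - camera$u0) / camera$f
  y <- (v - camera$v0) / (camera$s * camera$f)
  Dcam <- cbind(x, y, 1)
  D <- Dcam %*% camera$R             # R^T applied to rows
  D <- D / sqrt(rowSums(D^2))
  list(origin = camera_position(camera), D = D, W = W, H = H)
}

#' Render rotation silhouettes of an analytic solid
#'
#' Binary masks of the solid as seen by the geometry camera at each stage
#' angle, using exact ray-solid intersection at pixel centers. The solid
#' at stage angle `a` is rotated by `-a` about the axis, matching the
#' carving convention.
#'
#' @param solid an [analytic_solid()].
#' @param camera geometry [camera_model()] with a valid `image_size`.
#' @param angles rotation angles in degrees (default `seq(0, 355, by 5)`).
#' @param axis,axis_point rotation axis (default world +z through the
#'   origin).
#' @return A `silhouette_stack`.
#' @export
render_rotation_silhouettes <- function(solid, camera,
                                        angles = seq(0, 355, by = 5),
                                        axis = c(0, 0, 1),
                                        axis_point = c(0, 0, 0)) {
  rays <- .pixel_rays(camera)
  masks <- vector("list", length(angles))
  for (i in seq_along(angles)) {
    # object rotated by R(-a): test the inversely-rotated ray instead
    Rm <- rotation_about_axis(axis, angles[i])
    O <- matrix(drop(Rm %*% (rays$origin - axis_point)) + axis_point,
                nrow(rays$D), 3, byrow = TRUE)
    D <- rays$D %*% t(Rm)
    hit <- .ray_solid_hit(solid, O, D)$hit
    m <- matrix(0, rays$H, rays$W)
    m[cbind(rep(1:rays$H, rays$W), rep(1:rays$W, each = rays$H))] <- hit * 1
    if (!any(m == 1)) stop("out of frame: solid not visible at angle ",
                           angles[i])
    masks[[i]] <- m
  }
  assemble_stack(masks, camera = camera, axis = axis,
                 axis_point = axis_point, angles = angles)
}

#' Render a calibration-target image with ground truth
#'
#' Ray-traces the gridded cuboid from the camera: pixels hitting a
#' visible face are light except on grid lines (dark); background is
#' near black. Supersampled for smooth line profiles. Returns the exact
#' projected sub-pixel positions and labels of every junction on a
#' camera-facing face, plus the target mask (cuboid footprint) a user
#' would supply to the junction detector.
#'
#' @param camera a [camera_model()] with valid `image_size`.
#' @param cuboid a [calibration_cuboid()].
#' @param line_width grid line width in world units (default
#'   `0.12 * grid_spacing`).
#' @param supersample subpixel sampling factor per axis (default 3).
#' @return `list(image, truth, mask, visible_faces)`; `truth` is a fully
#'   labeled [junction_observations()].
#' @export
render_calibration_target <- function(camera, cuboid,
                                      line_width = 0.12 * cuboid$grid_spacing,
                                      supersample = 3) {
  W <- camera$image_size[1]; H <- camera$image_size[2]
  solid <- analytic_solid("cuboid", dims = c(cuboid$L, cuboid$W, cuboid$H))
  campos <- camera_position(camera)

  face_defs <- list(
    "+x" = list(n = c(1, 0, 0),  along = c(0, 1, 0),  width = cuboid$W),
    "+y" = list(n = c(0, 1, 0),  along = c(-1, 0, 0), width = cuboid$L),
    "-x" = list(n = c(-1, 0, 0), along = c(0, -1, 0), width = cuboid$W),
    "-y" = list(n = c(0, -1, 0), along = c(1, 0, 0),  width = cuboid$L))
  half_n <- c(cuboid$L / 2, cuboid$W / 2, cuboid$L / 2, cuboid$W / 2)
  visible <- vapply(seq_along(face_defs), function(i) {
    fc <- face_defs[[i]]
    ctr <- fc$n * half_n[i]
    sum(fc$n * (campos - ctr)) > 0
  }, logical(1))
  if (sum(visible) < 2)
    warning("fewer than 2 side faces visible: fewer junctions available")

  gp <- function(len) seq(-len / 2 + cuboid$grid_spacing / 2,
                          len / 2 - cuboid$grid_spacing / 2,
                          by = cuboid$grid_spacing)
  # supersampled rays
  ss <- supersample
  offs <- (seq_len(ss) - (ss + 1) / 2) / ss
  img <- matrix(0, H, W)
  msk <- matrix(0, H, W)
  for (ou in offs) for (ov in offs) {
    u <- rep(0:(W - 1) + ou, each = H)
    v <- rep(0:(H - 1) + ov, times = W)
    x <- (u - camera$u0) / camera$f
    y <- (v - camera$v0) / (camera$s * camera$f)
    D <- cbind(x, y, 1) %*% camera$R
    O <- matrix(campos, length(u), 3, byrow = TRUE)
    hh <- .ray_solid_hit(solid, O, D)
    val <- rep(0.03, length(u))   # background
    if (any(hh$hit)) {
      P <- O[hh$hit, , drop = FALSE] + hh$tmin[hh$hit] * D[hh$hit, , drop = FALSE]
      fv <- rep(0.85, nrow(P))    # lit face
      # which side face was struck (largest |coordinate|/half-extent)
      for (i in seq_along(face_defs)) {
        fc <- face_defs[[i]]
        d_face <- abs(drop(P %*% fc$n) - half_n[i])
        on_face <- d_face < 1e-9 * max(1, half_n[i])
        if (!any(on_face)) next
        a <- drop(P[on_face, , drop = FALSE] %*% fc$along)
        z <- P[on_face, 3]
        da <- do.call(pmin, lapply(gp(fc$width), function(g) abs(a - g)))
        dz <- do.call(pmin, lapply(gp(cuboid$H), function(g) abs(z - g)))
        on_line <- pmin(da, dz) <= line_width / 2
        fv[on_face][on_line] <- 0.15
      }
      val[hh$hit] <- fv
    }
    acc <- matrix(0, H, W)
    acc[cbind(rep(1:H, W), rep(1:W, each = H))] <- val
    img <- img + acc / (ss * ss)
    hitm <- matrix(0, H, W)
    hitm[cbind(rep(1:H, W), rep(1:W, each = H))] <- hh$hit * 1
    msk <- pmax(msk, hitm)
  }

  jt <- cuboid$junctions
  vis_names <- names(face_defs)[visible]
  sel <- jt$face %in% vis_names
  labels <- which(sel)
  uv <- project_point(camera, cuboid_junctions(cuboid, labels))
  inb <- uv[, 1] >= 0 & uv[, 1] <= W - 1 & uv[, 2] >= 0 & uv[, 2] <= H - 1
  truth <- junction_observations(uv[inb, , drop = FALSE], labels[inb],
                                 source_image = "synthetic render")
  list(image = img, truth = truth, mask = msk, visible_faces = vis_names)
}

#' Parametric action potential template
#'
#' Piecewise-linear optical action potential: baseline until
#' `upstroke_time`, linear rise over `upstroke_duration` to
#' `baseline + amplitude`, flat plateau for `plateau_duration`, then a
#' linear fall over `repolarization_duration` back to baseline. Chosen
#' over a biophysical model because every APD level has a closed-form
#' crossing time ([analytic_apd()]).
#'
#' @param upstroke_time onset, ms.
#' @param upstroke_duration rise time, ms (0 = instantaneous).
#' @param amplitude peak height above baseline.
#' @param plateau_duration ms.
#' @param repolarization_duration linear fall time, ms.
#' @param baseline resting value.
#' @export
ap_template <- function(upstroke_time = 20, upstroke_duration = 2,
                        amplitude = 1, plateau_duration = 30,
                        repolarization_duration = 100, baseline = 0) {
  stopifnot(upstroke_duration >= 0, plateau_duration >= 0,
            repolarization_duration > 0, amplitude > 0)
  structure(list(upstroke_time = upstroke_time,
                 upstroke_duration = upstroke_duration,
                 amplitude = amplitude,
                 plateau_duration = plateau_duration,
                 repolarization_duration = repolarization_duration,
                 baseline = baseline),
            class = "ap_template")
}

#' Evaluate an AP template at times (ms); vectorized
#' @param template an [ap_template()].
#' @param t_ms numeric vector/matrix of times in ms.
#' @export
ap_trace <- function(template, t_ms) {
  tt <- t_ms - template$upstroke_time
  up <- template$upstroke_duration
  pl <- template$plateau_duration
  rp <- template$repolarization_duration
  rise <- if (up > 0) tt / up else 1
  frac <- ifelse(tt < 0, 0,
          ifelse(tt < up, rise,
          ifelse(tt < up + pl, 1,
          ifelse(tt < up + pl + rp, 1 - (tt - up - pl) / rp, 0))))
  template$baseline + template$amplitude * frac
}

#' Closed-form APD of a template at a repolarization level
#'
#' Activation = midpoint of the linear upstroke (where the maximum
#' derivative convention lands on a linear rise); the level crossing
#' occurs a fraction `level` into the linear fall.
#'
#' @param template an [ap_template()].
#' @param level repolarization fraction (0.8 = APD80).
#' @return APD in ms.
#' @export
analytic_apd <- function(template, level = 0.8) {
  act <- template$upstroke_time + template$upstroke_duration / 2
  cross <- template$upstroke_time + template$upstroke_duration +
    template$plateau_duration + level * template$repolarization_duration
  cross - act
}

#' Sample a (noisy) action potential trace
#'
#' Deterministic given `seed`.
#'
#' @param template an [ap_template()].
#' @param n_samples number of samples.
#' @param sampling_rate Hz.
#' @param noise_sd additive Gaussian noise SD (default 0).
#' @param seed RNG seed (default 1).
#' @return Numeric vector of length `n_samples`.
#' @export
synth_action_potential <- function(template, n_samples, sampling_rate,
                                   noise_sd = 0, seed = 1) {
  t_ms <- (seq_len(n_samples) - 1) * 1000 / sampling_rate
  y <- ap_trace(template, t_ms)
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    y <- y + stats::rnorm(n_samples, sd = noise_sd)
  }
  y
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Activation / excitation patterns on a surface
#'
#' Defines the spatiotemporal ground-truth excitation driving the
#' synthetic movies. `plane_wave`: activation time linear in the
#' coordinate along `direction` with slope `1/speed`. `paced_focus`:
#' activation time proportional to distance from `origin` (radial
#' spread). `spiral`: an oscillation at `frequency` whose phase winds
#' once (chirality sign) around `core_lonlat` in the longitude/latitude
#' chart of the surface.
#'
#' @param kind `"plane_wave"`, `"paced_focus"` or `"spiral"`.
#' @param direction plane-wave direction (unit 3-vector).
#' @param speed conduction speed, world units per ms.
#' @param t0 earliest activation, ms.
#' @param origin focus origin (paced_focus), world units.
#' @param frequency spiral rotation frequency, Hz.
#' @param chirality +1 or -1 spiral sense.
#' @param core_lonlat spiral core `(lon, lat)` in degrees.
#' @export
activation_pattern <- function(kind = c("plane_wave", "paced_focus", "spiral"),
                               direction = c(0, 0, 1), speed = 0.05,
                               t0 = 10, origin = c(0, 0, 0),
                               frequency = 8, chirality = 1,
                               core_lonlat = c(0, 0)) {
  kind <- match.arg(kind)
  structure(list(kind = kind,
                 direction = direction / sqrt(sum(direction^2)),
                 speed = speed, t0 = t0, origin = as.numeric(origin),
                 frequency = frequency, chirality = chirality,
                 core_lonlat = as.numeric(core_lonlat)),
            class = "activation_pattern")
}

#' Ground-truth activation time of an onset pattern at world points
#'
#' Only defined for `plane_wave` and `paced_focus` patterns.
#' @param pattern an [activation_pattern()].
#' @param points N x 3 world points.
#' @param reference reference point mapped to `t0` (plane wave; default
#'   the minimum coordinate along the direction among `points`).
#' @return Activation times, ms.
#' @export
pattern_activation <- function(pattern, points, reference = NULL) {
  p <- as_point_matrix(points)
  if (pattern$kind == "plane_wave") {
    d <- drop(p %*% pattern$direction)
    d0 <- if (is.null(reference)) min(d)
          else sum(reference * pattern$direction)
    pattern$t0 + (d - d0) / pattern$speed
  } else if (pattern$kind == "paced_focus") {
    r <- sqrt(rowSums(sweep(p, 2, pattern$origin)^2))
    pattern$t0 + r / pattern$speed
  } else stop("spiral patterns have no single activation time")
}

# signal matrix (n points x n times) for a pattern on surface points
.pattern_signals <- function(pattern, points, t_ms, template,
                             sphere_param = NULL, reference = NULL) {
  if (pattern$kind %in% c("plane_wave", "paced_focus")) {
    act <- pattern_activation(pattern, points, reference)
    tt <- outer(-act, t_ms, `+`) + template$upstroke_time
    ap_trace(template, tt)
  } else {
    stopifnot(!is.null(sphere_param))
    psi <- atan2(sphere_param$lat - pattern$core_lonlat[2],
                 sphere_param$lon - pattern$core_lonlat[1])
    phase <- outer(-pattern$chirality * psi,
                   2 * pi * pattern$frequency * t_ms / 1000, `+`)
    template$baseline + template$amplitude * 0.5 * (1 + cos(phase))
  }
}

# (lon, lat) of world points about an axis through a center
.points_lonlat <- function(points, center, axis = c(0, 0, 1)) {
  d <- sweep(as_point_matrix(points), 2, center)
  ax <- axis / sqrt(sum(axis^2))
  ref <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * ax) * ax; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(ax[2] * e1[3] - ax[3] * e1[2],
          ax[3] * e1[1] - ax[1] * e1[3],
          ax[1] * e1[2] - ax[2] * e1[1])
  x <- drop(d %*% e1); y <- drop(d %*% e2); z <- drop(d %*% ax)
  r <- sqrt(x^2 + y^2 + z^2)
  list(lon = atan2(y, x) * 180 / pi,
       lat = asin(pmax(-1, pmin(1, z / pmax(r, 1e-300)))) * 180 / pi)
}

#' Ring of optical cameras around the world origin
#'
#' `n` cameras equally spaced in azimuth (90 degrees apart for the
#' standard four-camera rig), all at height `height` looking at the
#' origin.
#'
#' @param n number of cameras (default 4, ids A, B, C, ...).
#' @param distance camera distance from the origin, world units.
#' @param f focal length, pixels.
#' @param image_size `(width, height)` pixels (default 100 x 100).
#' @param height camera height, world units.
#' @param azimuth0 azimuth of camera A, degrees (default 45: corner-on
#'   to the calibration cuboid so two gridded faces are visible).
#' @param s,k1 intrinsics passed through.
#' @return Named list of [camera_model()].
#' @export
default_camera_ring <- function(n = 4, distance = 10, f = 250,
                                image_size = c(100, 100), height = 0,
                                azimuth0 = 45, s = 1, k1 = 0) {
  ids <- LETTERS[seq_len(n)]
  out <- lapply(seq_len(n), function(i) {
    az <- azimuth0 * pi / 180 + (i - 1) * 2 * pi / n
    pos <- c(distance * cos(az), distance * sin(az), height)
    look_at_camera(pos, c(0, 0, 0), f = f, s = s,
                   u0 = (image_size[1] - 1) / 2,
                   v0 = (image_size[2] - 1) / 2,
                   k1 = k1, image_size = image_size)
  })
  names(out) <- ids
  out
}

#' Synthesize per-camera optical movies from a surface pattern
#'
#' A known excitation pattern on the surface of an analytic solid is
#' rendered to each camera by exact ray casting: every pixel whose ray
#' hits the solid carries the pattern-driven action potential of its
#' surface point. Ground truth is returned for the pattern and, if a
#' mesh is supplied, for every mesh face (evaluated at the face
#' centroids).
#'
#' @param solid an [analytic_solid()].
#' @param pattern an [activation_pattern()].
#' @param cameras named list of [camera_model()].
#' @param duration_ms movie duration, ms.
#' @param sampling_rate Hz.
#' @param template an [ap_template()] (its `upstroke_time` is replaced by
#'   the pattern's activation times).
#' @param noise_sd additive Gaussian noise SD (default 0).
#' @param seed RNG seed for the noise (default 1).
#' @param mesh optional [surface_mesh()] for per-face ground truth.
#' @return `list(movies, ground_truth)`; `ground_truth` holds the
#'   pattern, and per-face `activation` (ms) and `signals` when a mesh
#'   is given.
#' @export
synth_camera_movies <- function(solid, pattern, cameras, duration_ms = 300,
                                sampling_rate = 1000,
                                template = ap_template(upstroke_time = 0),
                                noise_sd = 0, seed = 1, mesh = NULL) {
  t_ms <- seq(0, duration_ms, by = 1000 / sampling_rate)
  # plane waves enter the solid at its far point against the direction,
  # so the earliest activation is exactly the pattern's t0
  wave_ref <- if (pattern$kind == "plane_wave")
    solid$center - solid_support(solid, pattern$direction) * pattern$direction
  else pattern$origin
  movies <- list()
  for (ci in seq_along(cameras)) {
    cam <- cameras[[ci]]
    rays <- .pixel_rays(cam)
    O <- matrix(rays$origin, nrow(rays$D), 3, byrow = TRUE)
    hh <- .ray_solid_hit(solid, O, rays$D)
    mask <- matrix(0, rays$H, rays$W)
    lin <- cbind(rep(1:rays$H, rays$W), rep(1:rays$W, each = rays$H))
    mask[lin] <- hh$hit * 1
    P <- O[hh$hit, , drop = FALSE] +
      hh$tmin[hh$hit] * rays$D[hh$hit, , drop = FALSE]
    sp <- if (pattern$kind == "spiral")
      .points_lonlat(P, solid$center) else NULL
    sig <- .pattern_signals(pattern, P, t_ms, template, sp,
                            reference = wave_ref)
    frames <- array(0, c(rays$H, rays$W, length(t_ms)))
    M <- matrix(frames, ncol = length(t_ms))
    pix_lin <- lin[hh$hit, 1] + rays$H * (lin[hh$hit, 2] - 1)
    M[pix_lin, ] <- sig
    if (noise_sd > 0) {
      old <- .Random.seed_save(); set.seed(seed + ci)
      M[pix_lin, ] <- M[pix_lin, ] +
        stats::rnorm(length(pix_lin) * length(t_ms), sd = noise_sd)
      .Random.seed_restore(old)
    }
    movies[[names(cameras)[ci]]] <- optical_movie(
      array(M, c(rays$H, rays$W, length(t_ms))), sampling_rate,
      camera_id = names(cameras)[ci], mask = mask)
  }
  gt <- list(pattern = pattern, t_ms = t_ms, template = template)
  if (!is.null(mesh)) {
    ctr <- mesh$face_centroids
    if (pattern$kind != "spiral") {
      gt$activation <- pattern_activation(pattern, ctr,
                                          reference = wave_ref) +
        template$upstroke_duration / 2
      gt$signals <- .pattern_signals(pattern, ctr, t_ms, template,
                                     reference = wave_ref)
    } else {
      sp <- .points_lonlat(ctr, solid$center)
      gt$signals <- .pattern_signals(pattern, ctr, t_ms, template, sp)
      gt$core_lonlat <- pattern$core_lonlat
    }
  }
  list(movies = movies, ground_truth = gt)
}

#' Analytic spiral (wrapped-phase) test image
#'
#' `phase(u, v) = chirality * atan2(v - cv, u - cu)`, wrapped to
#' `(-pi, pi]`: a single phase singularity of the given chirality at the
#' center.
#'
#' @param shape `(H, W)` in pixels.
#' @param center `(u, v)` core position (0-based pixels).
#' @param chirality +1 or -1.
#' @return H x W matrix of wrapped phase.
#' @export
synth_spiral_phase_field <- function(shape, center, chirality = 1) {
  H <- shape[1]; W <- shape[2]
  stopifnot(center[1] >= 0, center[1] <= W - 1,
            center[2] >= 0, center[2] <= H - 1)
  u <- matrix(rep(0:(W - 1), each = H), H, W)
  v <- matrix(rep(0:(H - 1), times = W), H, W)
  .wrap_phase(chirality * atan2(v - center[2], u - center[1]))
}
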