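#' Pinhole camera model
#'
#' Constructs a perspective (pinhole) camera. The camera looks down its +z
#' axis; world points are mapped to the camera frame by \code{R \%*\% p + t}
#' and onto the sensor by the intrinsics: focal length \code{f} (pixels),
#' aspect ratio \code{s}, principal point \code{(u0, v0)}. A single radial
#' distortion coefficient \code{k1} acts on normalized image coordinates
#' (default 0: the panoramic rigs this models use long lenses with little to
#' no lens distortion). Pixel coordinates are 0-based, u right, v down, with
#' pixel centers at integer coordinates.
#'
#' @param R 3x3 orthonormal world-to-camera rotation matrix (det +1).
#' @param t translation 3-vector, world units.
#' @param f focal length in pixel units (> 0).
#' @param s aspect ratio (> 0); the effective vertical focal length is `s*f`.
#' @param u0,v0 principal point, pixels.
#' @param k1 first radial distortion coefficient (normalized coordinates).
#' @param image_size integer `(width, height)` in pixels.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(R, t, f, s = 1, u0, v0, k1 = 0,
                         image_size = c(NA_integer_, NA_integer_)) {
  R <- matrix(as.numeric(R), 3, 3)
  stopifnot(length(t) == 3, length(f) == 1, f > 0, s > 0)
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    stop("R is not orthonormal")
  if (det(R) < 0) stop("R must be a proper rotation (det = +1)")
  structure(list(R = R, t = as.numeric(t), f = as.numeric(f),
                 s = as.numeric(s), u0 = as.numeric(u0), v0 = as.numeric(v0),
                 k1 = as.numeric(k1), image_size = as.numeric(image_size)),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat("<camera_model>\n")
  cat("  f =", format(x$f), " s =", format(x$s),
      " (u0, v0) = (", format(x$u0), ",", format(x$v0), ")",
      " k1 =", format(x$k1), "\n")
  cat("  position:", paste(format(camera_position(x), digits = 4),
                           collapse = " "), "\n")
  cat("  image_size:", paste(x$image_size, collapse = " x "), "\n")
  invisible(x)
}

as_point_matrix <- function(p) {
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 3)
    p
  } else {
    stopifnot(length(p) == 3)
    matrix(as.numeric(p), 1, 3)
  }
}

#' Transform world points into the camera frame
#'
#' Applies the extrinsic (global-to-camera) transformation `R p + t`.
#'
#' @param camera a [camera_model()].
#' @param points 3-vector or N x 3 matrix of world points.
#' @return Same shape as `points`, in camera coordinates.
#' @export
world_to_camera <- function(camera, points) {
  p <- as_point_matrix(points)
  out <- p %*% t(camera$R) +
    matrix(camera$t, nrow(p), 3, byrow = TRUE)
  if (!is.matrix(points)) drop(out) else out
}

#' Inverse of [world_to_camera()]
#' @inheritParams world_to_camera
#' @export
camera_to_world <- function(camera, points) {
  p <- as_point_matrix(points)
  out <- (p - matrix(camera$t, nrow(p), 3, byrow = TRUE)) %*% camera$R
  if (!is.matrix(points)) drop(out) else out
}

#' Camera center in world coordinates
#' @param camera a [camera_model()].
#' @export
camera_position <- function(camera) {
  drop(-crossprod(camera$R, camera$t))
}

#' Camera viewing direction (optical axis) in the world frame
#'
#' The unit vector along the camera's +z axis expressed in world
#' coordinates; points from the camera into the scene. This is the camera
#' normal used by the angle-based face classification.
#'
#' @param camera a [camera_model()].
#' @export
camera_normal <- function(camera) {
  drop(crossprod(camera$R, c(0, 0, 1)))
}

#' Extrinsic transformation matrix `[R | t]` (3 x 4)
#' @param camera a [camera_model()].
#' @export
extrinsic_matrix <- function(camera) cbind(camera$R, camera$t)

#' Intrinsic matrix `K` (3 x 3)
#' @param camera a [camera_model()].
#' @export
intrinsic_matrix <- function(camera) {
  matrix(c(camera$f, 0, 0,
           0, camera$s * camera$f, 0,
           camera$u0, camera$v0, 1), 3, 3)
}

#' Full 3 x 4 projection matrix `K [R | t]`
#'
#' Only exact for `k1 = 0` (radial distortion is not linear).
#' @param camera a [camera_model()].
#' @export
projection_matrix <- function(camera) {
  intrinsic_matrix(camera) %*% extrinsic_matrix(camera)
}

#' Project world points onto the sensor
#'
#' Camera-frame coordinates are perspective-divided (`x = X/Z, y = Y/Z`),
#' radially distorted (`x' = x (1 + k1 r^2)`), then mapped through the
#' intrinsics: `u = f x' + u0`, `v = s f y' + v0`.
#'
#' @param camera a [camera_model()].
#' @param points 3-vector or N x 3 matrix of world points.
#' @param allow_behind if `TRUE`, points at or behind the camera plane
#'   (`Z <= 0`) yield `NA` rows instead of an error.
#' @return 2-vector or N x 2 matrix of `(u, v)` pixel coordinates.
#' @export
project_point <- function(camera, points, allow_behind = FALSE) {
  p <- as_point_matrix(points)
  pc <- p %*% t(camera$R) + matrix(camera$t, nrow(p), 3, byrow = TRUE)
  z <- pc[, 3]
  bad <- z <= 0
  if (any(bad) && !allow_behind)
    stop("unprojectable point: ", sum(bad), " point(s) at or behind the camera plane")
  z[bad] <- NA_real_
  x <- pc[, 1] / z
  y <- pc[, 2] / z
  if (camera$k1 != 0) {
    d <- 1 + camera$k1 * (x^2 + y^2)
    x <- x * d
    y <- y * d
  }
  uv <- cbind(u = camera$f * x + camera$u0,
              v = camera$s * camera$f * y + camera$v0)
  if (!is.matrix(points)) drop(uv) else uv
}

#' Rotation matrix about an arbitrary axis
#'
#' @param axis 3-vector (normalized internally).
#' @param degrees rotation angle, degrees (right-handed about `axis`).
#' @export
rotation_about_axis <- function(axis, degrees) {
  a <- axis / sqrt(sum(axis^2))
  th <- degrees * pi / 180
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Rodrigues vector (axis * angle, radians) -> rotation matrix
rotation_from_rodrigues <- function(r) {
  th <- sqrt(sum(r^2))
  if (th < 1e-14) return(diag(3))
  rotation_about_axis(r, th * 180 / pi)
}

# rotation matrix -> Rodrigues vector
rodrigues_from_rotation <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  th <- acos(ct)
  if (th < 1e-12) return(c(0, 0, 0))
  if (abs(pi - th) < 1e-6) {
    # near 180 degrees: axis from the symmetric part
    A <- (R + diag(3)) / 2
    a <- sqrt(pmax(diag(A), 0))
    i <- which.max(a)
    a <- A[, i] / a[i]
    return(th * a / sqrt(sum(a^2)))
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(th))
  th * ax
}

#' Apply a small pose correction to a calibrated camera
#'
#' Composes an extra rotation (x-y-z Euler angles, applied in the camera
#' frame) and translation with the existing pose. Used to nudge a
#' calibration when the projected mesh is visibly misaligned with the
#' optical images. Zero deltas return the camera unchanged.
#'
#' @param camera a [camera_model()].
#' @param delta_rotation Euler angles `(rx, ry, rz)` in degrees.
#' @param delta_translation 3-vector, world units (camera-frame offset).
#' @return Adjusted `camera_model`.
#' @export
adjust_camera_pose <- function(camera, delta_rotation = c(0, 0, 0),
                               delta_translation = c(0, 0, 0)) {
  stopifnot(length(delta_rotation) == 3, length(delta_translation) == 3)
  dR <- rotation_about_axis(c(0, 0, 1), delta_rotation[3]) %*%
    rotation_about_axis(c(0, 1, 0), delta_rotation[2]) %*%
    rotation_about_axis(c(1, 0, 0), delta_rotation[1])
  camera_model(R = dR %*% camera$R,
               t = drop(dR %*% camera$t) + as.numeric(delta_translation),
               f = camera$f, s = camera$s, u0 = camera$u0, v0 = camera$v0,
               k1 = camera$k1, image_size = camera$image_size)
}

#' Construct a camera looking at a target point
#'
#' Convenience constructor: places the camera at `position`, aims the
#' optical axis at `target`, and rolls the sensor so that `up` maps to
#' image-up (negative v).
#'
#' @param position,target 3-vectors, world units.
#' @param up approximate world up direction (default +z).
#' @inheritParams camera_model
#' @export
look_at_camera <- function(position, target = c(0, 0, 0), up = c(0, 0, 1),
                           f, s = 1, u0, v0, k1 = 0, image_size) {
  fwd <- target - position
  fwd <- fwd / sqrt(sum(fwd^2))
  right <- c(fwd[2] * up[3] - fwd[3] * up[2],
             fwd[3] * up[1] - fwd[1] * up[3],
             fwd[1] * up[2] - fwd[2] * up[1])
  # right = forward x up so that with v down the image is upright
  rn <- sqrt(sum(right^2))
  if (rn < 1e-12) stop("up direction parallel to viewing direction")
  right <- right / rn
  down <- c(fwd[2] * right[3] - fwd[3] * right[2],
            fwd[3] * right[1] - fwd[1] * right[3],
            fwd[1] * right[2] - fwd[2] * right[1])
  R <- rbind(right, down, fwd)
  dimnames(R) <- NULL
  camera_model(R = R, t = drop(-R %*% position), f = f, s = s,
               u0 = u0, v0 = v0, k1 = k1, image_size = image_size)
}
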