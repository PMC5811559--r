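# RQ decomposition A = U T with U upper-triangular (positive diagonal)
# and T orthonormal; used to split the DLT matrix into intrinsics and
# rotation.
.rq_decompose <- function(A) {
  E <- diag(3)[3:1, ]
  qrres <- qr(t(E %*% A))
  Q <- qr.Q(qrres)
  Rr <- qr.R(qrres)
  U <- E %*% t(Rr) %*% E
  T_ <- E %*% t(Q)
  D <- diag(sign(diag(U)))
  list(U = U %*% D, T = D %*% T_)
}

.labeled_correspondences <- function(obs, cuboid) {
  ok <- !is.na(obs$labels)
  if (!any(ok)) stop("empty observations: no labeled points")
  list(xy = obs$pixels[ok, , drop = FALSE],
       XYZ = cuboid_junctions(cuboid, obs$labels[ok]))
}

#' Direct linear (DLT) camera estimate
#'
#' Solves the homogeneous linear system for the 3 x 4 projection matrix
#' from labeled 2D-3D correspondences and decomposes it into intrinsics,
#' rotation and translation. Used to seed the nonlinear calibration; no
#' distortion is estimated (`k1 = 0`).
#'
#' @param obs a [junction_observations()] (labeled points used).
#' @param cuboid a [calibration_cuboid()].
#' @param image_size optional `(width, height)` carried into the model.
#' @return A [camera_model()].
#' @export
dlt_camera <- function(obs, cuboid, image_size = c(NA, NA)) {
  co <- .labeled_correspondences(obs, cuboid)
  n <- nrow(co$xy)
  if (n < 6) stop("underdetermined calibration: need >= 6 labeled points, got ", n)
  X <- co$XYZ; xy <- co$xy
  # normalize for conditioning
  cX <- colMeans(X); sX <- mean(sqrt(rowSums(sweep(X, 2, cX)^2)))
  cx <- colMeans(xy); sx <- mean(sqrt(rowSums(sweep(xy, 2, cx)^2)))
  if (sX < 1e-12 || sx < 1e-12)
    stop("underdetermined calibration: degenerate point configuration")
  Xn <- sweep(X, 2, cX) * (sqrt(3) / sX)
  xn <- sweep(xy, 2, cx) * (sqrt(2) / sx)
  A <- matrix(0, 2 * n, 12)
  Xh <- cbind(Xn, 1)
  A[seq(1, 2 * n, 2), 1:4] <- Xh
  A[seq(1, 2 * n, 2), 9:12] <- -xn[, 1] * Xh
  A[seq(2, 2 * n, 2), 5:8] <- Xh
  A[seq(2, 2 * n, 2), 9:12] <- -xn[, 2] * Xh
  sv <- svd(A, nu = 0, nv = 12)
  if (sv$d[11] / sv$d[1] < 1e-10)
    stop("underdetermined calibration: degenerate point configuration")
  Pn <- matrix(sv$v[, 12], 3, 4, byrow = TRUE)
  # undo normalization: x = Tx^-1 xn, X = TX^-1 Xn
  Tx <- rbind(c(sqrt(2) / sx, 0, -sqrt(2) / sx * cx[1]),
              c(0, sqrt(2) / sx, -sqrt(2) / sx * cx[2]),
              c(0, 0, 1))
  TX <- rbind(cbind(diag(3) * (sqrt(3) / sX), -sqrt(3) / sX * cX),
              c(0, 0, 0, 1))
  P <- solve(Tx) %*% Pn %*% TX
  if (det(P[, 1:3]) < 0) P <- -P
  dec <- .rq_decompose(P[, 1:3])
  K <- dec$U / dec$U[3, 3]
  R <- dec$T
  t <- drop(solve(dec$U, P[, 4]))
  # cheirality: observed points must sit in front of the camera
  depth <- cbind(X, 1) %*% c(P[3, ]) / dec$U[3, 3]
  if (stats::median(depth) < 0)
    stop("underdetermined calibration: solution places points behind the camera")
  camera_model(R = R, t = t, f = K[1, 1], s = K[2, 2] / K[1, 1],
               u0 = K[1, 3], v0 = K[2, 3], k1 = 0, image_size = image_size)
}

.camera_to_params <- function(camera, estimate_k1) {
  p <- c(rodrigues_from_rotation(camera$R), camera$t,
         camera$f, camera$s, camera$u0, camera$v0)
  if (estimate_k1) p <- c(p, camera$k1)
  p
}

.params_to_camera <- function(p, image_size, estimate_k1) {
  camera_model(R = rotation_from_rodrigues(p[1:3]), t = p[4:6],
               f = p[7], s = p[8], u0 = p[9], v0 = p[10],
               k1 = if (estimate_k1) p[11] else 0,
               image_size = image_size)
}

#' Calibrate a camera from labeled junction observations
#'
#' Levenberg-Marquardt minimization of the summed squared reprojection
#' error over the extrinsic (Rodrigues rotation vector, translation) and
#' intrinsic (`f`, `s`, `u0`, `v0`, optionally `k1`) parameters. The 3D
#' junction coordinates are held fixed. If no initial model is supplied, a
#' direct linear estimate ([dlt_camera()]) seeds the optimization.
#' Convergence: relative residual change below `1e-10` or 200 iterations.
#'
#' @param obs a [junction_observations()]; at least 6 labeled points.
#' @param cuboid a [calibration_cuboid()].
#' @param init optional initial [camera_model()].
#' @param estimate_k1 also estimate the radial distortion coefficient
#'   (default `FALSE`: frozen at 0).
#' @param image_size optional `(width, height)` carried into the model.
#' @return A calibrated [camera_model()].
#' @export
calibrate_camera <- function(obs, cuboid, init = NULL, estimate_k1 = FALSE,
                             image_size = NULL) {
  co <- .labeled_correspondences(obs, cuboid)
  if (nrow(co$xy) < 6)
    stop("underdetermined calibration: need >= 6 labeled points, got ",
         nrow(co$xy))
  if (is.null(image_size))
    image_size <- if (!is.null(init)) init$image_size else c(NA, NA)
  if (is.null(init)) init <- dlt_camera(obs, cuboid, image_size)
  resid_fn <- function(p) {
    cam <- tryCatch(.params_to_camera(p, image_size, estimate_k1),
                    error = function(e) NULL)
    if (is.null(cam)) return(rep(1e6, 2 * nrow(co$xy)))
    uv <- project_point(cam, co$XYZ, allow_behind = TRUE)
    r <- as.numeric(t(uv - co$xy))
    r[!is.finite(r)] <- 1e6
    r
  }
  fit <- minpack.lm::nls.lm(
    par = .camera_to_params(init, estimate_k1), fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      ftol = 1e-10, ptol = 1e-12, maxiter = 200))
  .params_to_camera(fit$par, image_size, estimate_k1)
}

#' Root-mean-square reprojection error
#'
#' RMSE over the per-point Euclidean reprojection distances of all labeled
#' observations: `sqrt(mean(|proj - obs|^2))`, in pixels.
#'
#' @param camera a [camera_model()].
#' @param obs a [junction_observations()].
#' @param cuboid a [calibration_cuboid()].
#' @return Non-negative scalar, pixels; 0 iff every projection matches.
#' @export
reprojection_rmse <- function(camera, obs, cuboid) {
  co <- .labeled_correspondences(obs, cuboid)
  uv <- project_point(camera, co$XYZ, allow_behind = TRUE)
  sqrt(mean(rowSums((uv - co$xy)^2)))
}

#' Read / write a camera model as YAML
#' @param path file path.
#' @rdname camera_yaml
#' @export
read_camera_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  camera_model(R = matrix(unlist(y$R), 3, 3, byrow = TRUE),
               t = unlist(y$t), f = y$f, s = y$s, u0 = y$u0, v0 = y$v0,
               k1 = y$k1 %||% 0,
               image_size = unlist(y$image_size) %||% c(NA, NA))
}

#' @param camera a [camera_model()].
#' @rdname camera_yaml
#' @export
write_camera_yaml <- function(camera, path) {
  y <- list(R = lapply(1:3, function(i) as.numeric(camera$R[i, ])),
            t = as.numeric(camera$t), f = camera$f, s = camera$s,
            u0 = camera$u0, v0 = camera$v0, k1 = camera$k1,
            image_size = as.numeric(camera$image_size))
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
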