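#' Detect grid junctions in a calibration image
#'
#' Junction (grid-line crossing) detection restricted to a user-supplied
#' target mask. After Gaussian blurring at the line scale, a crossing of
#' two dark grid lines is a strict 2D intensity minimum with positive
#' curvature along both line directions, while an isolated line is a
#' ridge (near-zero curvature along it). Candidates are local maxima of
#' the determinant-of-Hessian response gated on both curvatures, and are
#' refined to sub-pixel accuracy by a Newton step on the blurred
#' intensity (whose gradient vanishes exactly at the crossing).
#' Detections closer together than `min_separation` are suppressed
#' (strongest kept); by default the separation is half the median
#' nearest-neighbour distance of the candidates, i.e. roughly half the
#' projected grid pitch.
#'
#' @param image numeric matrix `[row, col]`, grayscale; any range.
#' @param target_mask binary matrix, same shape; 1 = search region. The
#'   mask is eroded by `2 * sigma` pixels so silhouette boundaries do not
#'   trigger detections.
#' @param sigma Gaussian blur scale in pixels, about the grid-line
#'   half-width (default 2).
#' @param threshold response threshold as a fraction of the maximum
#'   determinant-of-Hessian response inside the mask.
#' @param min_separation minimum distance between detections, pixels;
#'   `NULL` = half the median candidate nearest-neighbour distance.
#' @param dark_lines are grid lines darker than the faces? (default
#'   `TRUE`).
#' @return N x 2 matrix of sub-pixel `(u, v)` coordinates (0-based, u
#'   right, v down), ordered by decreasing response.
#' @export
detect_junctions <- function(image, target_mask = NULL, sigma = 2,
                             threshold = 0.05, min_separation = NULL,
                             dark_lines = TRUE) {
  img <- as.matrix(image)
  if (is.null(target_mask)) target_mask <- matrix(1, nrow(img), ncol(img))
  msk <- as.matrix(target_mask) > 0
  stopifnot(all(dim(img) == dim(msk)))
  no_hits <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("u", "v")))
  if (!any(msk)) {
    warning("empty target mask: no junctions to detect")
    return(no_hits)
  }
  rng <- range(img)
  if (diff(rng) == 0) return(no_hits)
  img <- (img - rng[1]) / diff(rng)
  if (dark_lines) img <- 1 - img   # crossings become maxima
  f <- EBImage::gblur(img, sigma = sigma)

  # erode the mask so boundaries of the target cannot respond
  er <- ceiling(2 * sigma)
  if (er > 0) {
    brush <- EBImage::makeBrush(2 * er + 1, shape = "disc")
    msk <- EBImage::erode(msk * 1, brush) > 0
    if (!any(msk)) {
      warning("target mask empty after erosion: no junctions to detect")
      return(no_hits)
    }
  }

  n <- nrow(f); m <- ncol(f)
  z <- matrix(0, n, m)
  fvv <- z; fuu <- z; fuv <- z; gv <- z; gu <- z
  fvv[2:(n - 1), ] <- f[3:n, ] - 2 * f[2:(n - 1), ] + f[1:(n - 2), ]
  fuu[, 2:(m - 1)] <- f[, 3:m] - 2 * f[, 2:(m - 1)] + f[, 1:(m - 2)]
  gv[2:(n - 1), ] <- (f[3:n, ] - f[1:(n - 2), ]) / 2
  gu[, 2:(m - 1)] <- (f[, 3:m] - f[, 1:(m - 2)]) / 2
  fuv[2:(n - 1), 2:(m - 1)] <-
    (f[3:n, 3:m] - f[3:n, 1:(m - 2)] - f[1:(n - 2), 3:m] +
       f[1:(n - 2), 1:(m - 2)]) / 4
  # crossings (maxima of f): both curvatures negative, det of Hessian > 0
  resp <- fuu * fvv - fuv^2
  resp[fuu >= 0 | fvv >= 0] <- 0
  resp[!msk] <- 0
  resp_max <- max(resp)
  if (resp_max <= 0) return(no_hits)

  cand <- which(resp > threshold * resp_max, arr.ind = TRUE)
  cand <- cand[cand[, 1] > 1 & cand[, 1] < n & cand[, 2] > 1 & cand[, 2] < m,
               , drop = FALSE]
  # strict local maxima of the blurred intensity on a 3x3 neighbourhood
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    nb <- f[(r - 1):(r + 1), (c - 1):(c + 1)]
    keep[i] <- f[r, c] == max(nb) && sum(nb == f[r, c]) == 1
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(no_hits)
  strength <- resp[cand]

  pts <- cbind(u = cand[, 2] - 1, v = cand[, 1] - 1)
  if (is.null(min_separation)) {
    if (nrow(pts) > 1) {
      d <- as.matrix(stats::dist(pts))
      diag(d) <- Inf
      min_separation <- stats::median(apply(d, 1, min)) / 2
    } else min_separation <- 0
  }
  ord <- order(strength, decreasing = TRUE)
  sel <- integer(0)
  for (i in ord) {
    if (length(sel) == 0 ||
        all((pts[sel, 1] - pts[i, 1])^2 + (pts[sel, 2] - pts[i, 2])^2 >=
            min_separation^2)) sel <- c(sel, i)
  }
  cand <- cand[sel, , drop = FALSE]

  # sub-pixel refinement: Newton step on the blurred intensity
  out <- matrix(NA_real_, nrow(cand), 2, dimnames = list(NULL, c("u", "v")))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    H <- matrix(c(fuu[r, c], fuv[r, c], fuv[r, c], fvv[r, c]), 2, 2)
    off <- c(0, 0)
    if (all(is.finite(H)) && abs(det(H)) > 1e-14) {
      off <- -solve(H, c(gu[r, c], gv[r, c]))
      if (any(abs(off) > 1)) off <- pmax(pmin(off, 1), -1)
    }
    out[i, ] <- c(c - 1 + off[1], r - 1 + off[2])
  }
  out
}

# ccw order of the side faces seen from +z; the ccw-next face of an
# adjacent visible pair appears on the RIGHT in an upright outside view
.face_order <- c("+x", "+y", "-x", "-y")

# arrange points into an n_rows x n_cols grid by image position:
# rows = bands of increasing v (top row first), columns by increasing u
.arrange_grid <- function(points, n_rows, n_cols) {
  stopifnot(nrow(points) == n_rows * n_cols)
  ord <- order(points[, 2])
  idx <- matrix(NA_integer_, n_rows, n_cols)
  for (r in seq_len(n_rows)) {
    band <- ord[((r - 1) * n_cols + 1):(r * n_cols)]
    idx[r, ] <- band[order(points[band, 1])]
  }
  idx
}

# labels of the cuboid junction with given face/row/col
.junction_label <- function(cuboid, face, row, col) {
  j <- cuboid$junctions
  which(j$face == face & j$row == row & j$col == col)
}

#' Label detected junctions against the cuboid grid
#'
#' Assigns each detected 2D point the index of its 3D grid junction.
#' With no anchors the full two-face grid must be visible and the camera
#' roughly upright: the points are arranged into image rows and columns,
#' each of the four adjacent face pairs is hypothesized as the visible
#' pair (the counterclockwise-next face of a pair appears on the right
#' when viewed from outside), and the hypothesis whose direct linear
#' calibration reprojects with the smallest error wins. With two anchors
#' (top-left and bottom-right junction indices) the spanned sub-grid is
#' labeled directly, which also covers partially visible grids.
#'
#' @param points N x 2 matrix of `(u, v)` detections.
#' @param cuboid a [calibration_cuboid()].
#' @param anchors optional list of two `list(point = c(u, v), junction = i)`
#'   entries: the top-left and bottom-right visible junctions.
#' @return A [junction_observations()] with all points labeled.
#' @export
label_junctions <- function(points, cuboid, anchors = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0) stop("labeling failure: no points")

  if (!is.null(anchors)) {
    stopifnot(length(anchors) %in% c(1L, 2L))
    if (length(anchors) == 1L && n == 1L) {
      return(junction_observations(points, anchors[[1]]$junction))
    }
    jt <- cuboid$junctions
    a1 <- jt[anchors[[1]]$junction, ]  # top-left
    a2 <- jt[anchors[[2]]$junction, ]  # bottom-right
    fi1 <- match(a1$face, .face_order)
    fi2 <- match(a2$face, .face_order)
    if (a1$row < a2$row)
      stop("labeling failure: top-left anchor below bottom-right anchor")
    ncol_face <- function(f) max(jt$col[jt$face == f])
    if (fi1 == fi2) {
      if (a2$col < a1$col) stop("labeling failure: anchors reversed in columns")
      cols <- lapply(a1$col:a2$col, function(cc) c(a1$face, cc))
    } else if ((fi1 %% 4) + 1 == fi2) {
      cols <- c(lapply(a1$col:ncol_face(a1$face), function(cc) c(a1$face, cc)),
                lapply(1:a2$col, function(cc) c(a2$face, cc)))
    } else {
      stop("labeling failure: anchor faces are not adjacent in view order")
    }
    rows <- a1$row:a2$row  # top (high z) to bottom
    if (length(rows) * length(cols) != n)
      stop("labeling failure: grid spanned by anchors has ",
           length(rows) * length(cols), " junctions but ", n,
           " points were supplied")
    idx <- .arrange_grid(points, length(rows), length(cols))
    labels <- integer(n)
    for (r in seq_along(rows)) for (cc in seq_along(cols)) {
      lab <- .junction_label(cuboid, cols[[cc]][1], rows[r],
                             as.integer(cols[[cc]][2]))
      labels[idx[r, cc]] <- lab
    }
    return(junction_observations(points, labels))
  }

  # no anchors: full two-face grid assumed visible
  jt <- cuboid$junctions
  n_rows <- max(jt$row)
  best <- NULL
  for (left_i in seq_along(.face_order)) {
    left <- .face_order[left_i]
    right <- .face_order[(left_i %% 4) + 1]
    nc_l <- max(jt$col[jt$face == left])
    nc_r <- max(jt$col[jt$face == right])
    if (n != n_rows * (nc_l + nc_r)) next
    idx <- .arrange_grid(points, n_rows, nc_l + nc_r)
    labels <- integer(n)
    for (r in seq_len(n_rows)) for (cc in seq_len(nc_l + nc_r)) {
      face <- if (cc <= nc_l) left else right
      col <- if (cc <= nc_l) cc else cc - nc_l
      labels[idx[r, cc]] <- .junction_label(cuboid, face, n_rows + 1 - r, col)
    }
    obs <- junction_observations(points, labels)
    rmse <- tryCatch({
      cam <- dlt_camera(obs, cuboid)
      reprojection_rmse(cam, obs, cuboid)
    }, error = function(e) Inf)
    if (is.null(best) || rmse < best$rmse)
      best <- list(obs = obs, rmse = rmse)
  }
  if (is.null(best))
    stop("labeling failure: point count (", n,
         ") does not match any two-face grid of this cuboid")
  if (!is.finite(best$rmse))
    stop("labeling failure: no hypothesis admits a valid calibration")
  best$obs
}
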