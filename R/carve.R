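#' Occupancy volume from visual-hull carving
#'
#' Regular grid of finest-level octree cells. Cell values: 1 = inside the
#' visual hull, 0 = outside, 0.5 = boundary cell at maximum depth (the
#' isosurface passes through these).
#'
#' @param origin minimum corner of the volume, world units.
#' @param extent edge lengths (3-vector), world units.
#' @param occupancy 3D array of cell values in `{0, 0.5, 1}`.
#' @export
occupancy_volume <- function(origin, extent, occupancy) {
  stopifnot(length(origin) == 3, length(extent) == 3, all(extent > 0),
            length(dim(occupancy)) == 3)
  structure(list(origin = as.numeric(origin), extent = as.numeric(extent),
                 resolution = extent[1] / dim(occupancy)[1],
                 occupancy = occupancy),
            class = "occupancy_volume")
}

#' @export
print.occupancy_volume <- function(x, ...) {
  d <- dim(x$occupancy)
  cat("<occupancy_volume> ", paste(d, collapse = " x "),
      " cells (resolution ", format(x$resolution, digits = 4), "), ",
      "inside ", sum(x$occupancy == 1), ", boundary ",
      sum(x$occupancy == 0.5), "\n", sep = "")
  invisible(x)
}

#' Estimated volume enclosed by the carved hull
#'
#' Inside cells count fully, boundary cells count half.
#' @param volume an [occupancy_volume()].
#' @export
carved_volume <- function(volume) {
  h <- volume$extent / dim(volume$occupancy)
  (sum(volume$occupancy == 1) + 0.5 * sum(volume$occupancy == 0.5)) *
    prod(h)
}

# rotate world points into the frame of the silhouette at `angle`:
# the stage turns the object by R(-angle), so a material point p appears
# at R(-angle) p in the image taken at that angle
.rotate_for_angle <- function(points, angle, axis, axis_point) {
  Rm <- rotation_about_axis(axis, -angle)
  sweep(sweep(points, 2, axis_point) %*% t(Rm), 2, axis_point, `+`)
}

#' Test world points against every silhouette
#'
#' A point is inside the visual hull iff, for every rotation angle, its
#' projection through the geometry camera lands on a silhouette (heart)
#' pixel. Projections falling outside the image, or behind the camera,
#' count as outside. Silhouette lookup is nearest-pixel.
#'
#' @param points N x 3 matrix of world points.
#' @param stack a `silhouette_stack`.
#' @return Logical vector of length N.
#' @export
points_in_hull <- function(points, stack) {
  points <- as_point_matrix(points)
  n <- nrow(points)
  alive <- rep(TRUE, n)
  H <- nrow(stack$masks[[1]]); W <- ncol(stack$masks[[1]])
  for (i in seq_along(stack$angles)) {
    if (!any(alive)) break
    p <- .rotate_for_angle(points[alive, , drop = FALSE], stack$angles[i],
                           stack$axis, stack$axis_point)
    uv <- project_point(stack$camera, p, allow_behind = TRUE)
    col <- round(uv[, 1]) + 1
    row <- round(uv[, 2]) + 1
    ok <- is.finite(col) & is.finite(row) &
      col >= 1 & col <= W & row >= 1 & row <= H
    ok[ok] <- stack$masks[[i]][cbind(row[ok], col[ok])] == 1
    alive[alive] <- ok
  }
  alive
}

#' Classify one voxel against the silhouette stack
#'
#' The eight corners are tested with [points_in_hull()]: all inside ->
#' `"inside"`, all outside -> `"outside"`, mixed -> `"boundary"`.
#'
#' @param corners 8 x 3 matrix of the voxel corner world coordinates.
#' @param stack a `silhouette_stack`.
#' @return `"inside"`, `"outside"` or `"boundary"`.
#' @export
classify_voxel <- function(corners, stack) {
  corners <- as.matrix(corners)
  stopifnot(nrow(corners) == 8, ncol(corners) == 3)
  ins <- points_in_hull(corners, stack)
  if (all(ins)) "inside" else if (!any(ins)) "outside" else "boundary"
}

# summed-area tables of the masks, for O(1) "any heart pixel in rect?"
.mask_sat <- function(mask) {
  s <- apply(apply(mask, 2, cumsum), 1, cumsum)
  # s is transposed by the second apply; fix orientation
  t(s)
}

.sat_sum <- function(sat, r1, r2, c1, c2) {
  a <- sat[cbind(r2, c2)]
  b <- ifelse(r1 > 1, sat[cbind(pmax(r1 - 1, 1), c2)], 0)
  cc <- ifelse(c1 > 1, sat[cbind(r2, pmax(c1 - 1, 1))], 0)
  d <- ifelse(r1 > 1 & c1 > 1, sat[cbind(pmax(r1 - 1, 1), pmax(c1 - 1, 1))], 0)
  a - b - cc + d
}

#' Default carving bounds from the silhouette stack
#'
#' A cube centered on the rotation-axis point, slightly larger than the
#' object: side = `scale` x the largest silhouette extent back-projected
#' to the axis depth.
#'
#' @param stack a `silhouette_stack`.
#' @param scale enlargement factor (default 1.2).
#' @return `list(origin, extent)` of an axis-aligned cube.
#' @export
default_carve_bounds <- function(stack, scale = 1.2) {
  cam <- stack$camera
  depth <- sum((stack$axis_point - camera_position(cam)) * camera_normal(cam))
  half <- 0
  for (m in stack$masks) {
    idx <- which(m == 1, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    u <- idx[, 2] - 1; v <- idx[, 1] - 1
    du <- max(abs(u - cam$u0)) / cam$f * depth
    dv <- max(abs(v - cam$v0)) / (cam$s * cam$f) * depth
    half <- max(half, du, dv)
  }
  if (half == 0) stop("degenerate silhouette: no foreground pixels")
  side <- scale * 2 * half
  list(origin = stack$axis_point - side / 2, extent = rep(side, 3))
}

#' Carve the visual hull with an octree
#'
#' Recursive space carving: a cube slightly larger than the object is
#' subdivided into eight voxels; voxel corners are projected onto every
#' silhouette (rotating the volume between views). Voxels whose corners
#' are all inside stay inside; voxels that provably project outside some
#' silhouette are discarded; the rest are subdivided until `max_depth`,
#' where mixed voxels become boundary cells (occupancy 0.5). For convex
#' silhouettes the result is cell-for-cell identical to brute-force
#' classification of the full finest grid.
#'
#' @param stack a `silhouette_stack`; all masks must be non-empty.
#' @param bounds `list(origin, extent)`; `NULL` uses
#'   [default_carve_bounds()].
#' @param max_depth octree depth; the finest grid is `2^max_depth` cells
#'   per axis (default 7, i.e. 128^3).
#' @return An [occupancy_volume()].
#' @export
carve_visual_hull <- function(stack, bounds = NULL, max_depth = 7) {
  stopifnot(max_depth >= 1)
  for (m in stack$masks)
    if (!any(m == 1)) stop("degenerate silhouette: empty mask in stack")
  if (is.null(bounds)) bounds <- default_carve_bounds(stack)
  origin <- as.numeric(bounds$origin)
  extent <- as.numeric(bounds$extent)
  sats <- lapply(stack$masks, .mask_sat)
  H <- nrow(stack$masks[[1]]); W <- ncol(stack$masks[[1]])
  nf <- 2^max_depth
  occ <- array(0, dim = c(nf, nf, nf))

  # active cells per level as 1-based integer index triples
  cells <- as.matrix(expand.grid(i = 1:2, j = 1:2, k = 1:2))
  for (level in 1:max_depth) {
    nl <- 2^level
    h <- extent / nl
    # unique corner lattice points of the active cells
    m <- nrow(cells)
    if (m == 0) break
    offs <- as.matrix(expand.grid(di = 0:1, dj = 0:1, dk = 0:1))
    gid <- matrix(0, m, 8)
    for (cidx in 1:8) {
      ci <- cells[, 1] - 1 + offs[cidx, 1]
      cj <- cells[, 2] - 1 + offs[cidx, 2]
      ck <- cells[, 3] - 1 + offs[cidx, 3]
      gid[, cidx] <- ci + (nl + 1) * (cj + (nl + 1) * ck)
    }
    ug <- unique(as.vector(gid))
    ci <- ug %% (nl + 1)
    cj <- (ug %/% (nl + 1)) %% (nl + 1)
    ck <- ug %/% ((nl + 1)^2)
    pts <- cbind(origin[1] + ci * h[1],
                 origin[2] + cj * h[2],
                 origin[3] + ck * h[3])
    ins_u <- points_in_hull(pts, stack)
    ins <- matrix(ins_u[match(as.vector(gid), ug)], m, 8)
    n_in <- rowSums(ins)

    full <- n_in == 8
    mixed <- n_in > 0 & n_in < 8
    empty_corners <- n_in == 0

    # conservative pruning of all-outside-corner cells: discard only if
    # the cell's projected bounding box misses some silhouette entirely
    prune <- rep(FALSE, m)
    if (any(empty_corners) && level < max_depth) {
      cand <- which(empty_corners)
      undecided <- rep(TRUE, length(cand))
      for (vi in seq_along(stack$angles)) {
        if (!any(undecided)) break
        rows <- cand[undecided]
        corner_pts <- NULL
        uu <- matrix(NA_real_, length(rows), 8)
        vv <- matrix(NA_real_, length(rows), 8)
        behind <- rep(FALSE, length(rows))
        for (cidx in 1:8) {
          p <- cbind(origin[1] + (cells[rows, 1] - 1 + offs[cidx, 1]) * h[1],
                     origin[2] + (cells[rows, 2] - 1 + offs[cidx, 2]) * h[2],
                     origin[3] + (cells[rows, 3] - 1 + offs[cidx, 3]) * h[3])
          p <- .rotate_for_angle(p, stack$angles[vi], stack$axis,
                                 stack$axis_point)
          uv <- project_point(stack$camera, p, allow_behind = TRUE)
          behind <- behind | !is.finite(uv[, 1])
          uu[, cidx] <- uv[, 1]
          vv[, cidx] <- uv[, 2]
        }
        c1 <- pmax(floor(apply(uu, 1, min)) + 1, 1)
        c2 <- pmin(ceiling(apply(uu, 1, max)) + 1, W)
        r1 <- pmax(floor(apply(vv, 1, min)) + 1, 1)
        r2 <- pmin(ceiling(apply(vv, 1, max)) + 1, H)
        off_image <- !behind & (c1 > c2 | r1 > r2 |
                                  c2 < 1 | r2 < 1 | c1 > W | r1 > H)
        cnt <- rep(1, length(rows))
        inb <- !behind & !off_image
        if (any(inb))
          cnt[inb] <- .sat_sum(sats[[vi]], r1[inb], r2[inb], c1[inb], c2[inb])
        miss <- (off_image | (!behind & cnt == 0))
        prune[rows[miss]] <- TRUE
        undecided[undecided][miss] <- FALSE
      }
    }

    scale_f <- nf / nl  # finest cells per cell edge at this level
    fill <- function(rowsel, value) {
      for (r in rowsel) {
        i0 <- (cells[r, 1] - 1) * scale_f
        j0 <- (cells[r, 2] - 1) * scale_f
        k0 <- (cells[r, 3] - 1) * scale_f
        occ[(i0 + 1):(i0 + scale_f),
            (j0 + 1):(j0 + scale_f),
            (k0 + 1):(k0 + scale_f)] <<- value
      }
    }
    fill(which(full), 1)
    if (level == max_depth) {
      fill(which(mixed), 0.5)
      break
    }
    subdiv <- which(mixed | (empty_corners & !prune))
    if (length(subdiv) == 0) break
    base <- cells[subdiv, , drop = FALSE] * 2L
    kids <- vector("list", 8)
    for (cidx in 1:8) {
      kids[[cidx]] <- cbind(base[, 1] - 1L + offs[cidx, 1],
                            base[, 2] - 1L + offs[cidx, 2],
                            base[, 3] - 1L + offs[cidx, 3])
    }
    cells <- do.call(rbind, kids)
  }
  occupancy_volume(origin, extent, occ)
}
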