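#' Gridded calibration cuboid
#'
#' Describes the rectangular cuboid calibration target. The world origin is
#' the cuboid center, +z along the height axis. A square grid is drawn on
#' the four outward-facing side faces; grid lines are inset
#' `grid_spacing / 2` from each face border and spaced `grid_spacing`, so a
#' 1 x 1 x 2 inch cuboid with 0.25 inch spacing carries 4 x 8 = 32 grid
#' intersections per side face (64 over any two adjacent faces, the view
#' used for calibration).
#'
#' @param L,W,H edge lengths along x, y, z; world units (rabbit-scale
#'   default: 1 x 1 x 2 inch).
#' @param grid_spacing spacing between grid lines, world units.
#' @return An object of class `calibration_cuboid` with a `junctions` table
#'   (columns `x, y, z, face, row, col`; one row per grid intersection,
#'   label = row number).
#' @export
calibration_cuboid <- function(L = 1, W = 1, H = 2, grid_spacing = 0.25) {
  stopifnot(L > 0, W > 0, H > 0, grid_spacing > 0,
            grid_spacing < min(L, W, H))
  grid_pos <- function(len) {
    seq(-len / 2 + grid_spacing / 2, len / 2 - grid_spacing / 2,
        by = grid_spacing)
  }
  zs <- grid_pos(H)
  # face normals +x, +y, -x, -y; in-face column axis chosen so that viewed
  # from outside with +z up, columns increase left to right
  faces <- list(
    "+x" = list(n = c(1, 0, 0),  along = c(0, 1, 0),  width = W),
    "+y" = list(n = c(0, 1, 0),  along = c(-1, 0, 0), width = L),
    "-x" = list(n = c(-1, 0, 0), along = c(0, -1, 0), width = W),
    "-y" = list(n = c(0, -1, 0), along = c(1, 0, 0),  width = L))
  rows <- list()
  for (fi in seq_along(faces)) {
    fc <- faces[[fi]]
    off <- fc$n * ifelse(abs(fc$n[1]) > 0, L / 2, W / 2)
    us <- grid_pos(fc$width)
    g <- expand.grid(col = seq_along(us), row = seq_along(zs))
    pts <- matrix(off, nrow(g), 3, byrow = TRUE) +
      outer(us[g$col], fc$along) +
      outer(zs[g$row], c(0, 0, 1))
    rows[[fi]] <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                             face = names(faces)[fi],
                             row = g$row, col = g$col,
                             stringsAsFactors = FALSE)
  }
  junctions <- do.call(rbind, rows)
  structure(list(L = L, W = W, H = H, grid_spacing = grid_spacing,
                 junctions = junctions),
            class = "calibration_cuboid")
}

#' @export
print.calibration_cuboid <- function(x, ...) {
  cat("<calibration_cuboid> ", x$L, "x", x$W, "x", x$H,
      " (grid spacing ", x$grid_spacing, "), ",
      nrow(x$junctions), " grid junctions\n", sep = "")
  invisible(x)
}

#' 3D coordinates of the cuboid grid junctions
#' @param cuboid a [calibration_cuboid()].
#' @param labels optional junction labels (row indices); default all.
#' @return N x 3 matrix of world coordinates.
#' @export
cuboid_junctions <- function(cuboid, labels = NULL) {
  j <- cuboid$junctions
  if (!is.null(labels)) j <- j[labels, , drop = FALSE]
  as.matrix(j[, c("x", "y", "z")])
}

#' Read / write a cuboid description as YAML
#' @param path file path.
#' @rdname cuboid_yaml
#' @export
read_cuboid_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  calibration_cuboid(L = y$L, W = y$W, H = y$H,
                     grid_spacing = y$grid_spacing)
}

#' @param cuboid a [calibration_cuboid()].
#' @rdname cuboid_yaml
#' @export
write_cuboid_yaml <- function(cuboid, path) {
  yaml::write_yaml(cuboid[c("L", "W", "H", "grid_spacing")], path)
  invisible(path)
}

#' Junction observations for one calibration image
#'
#' Pairs detected 2D sub-pixel junction locations with labels indexing the
#' cuboid's 3D junction table.
#'
#' @param pixels N x 2 matrix of `(u, v)` image coordinates.
#' @param labels integer vector (NA = unlabeled); labeled entries unique.
#' @param source_image optional provenance string.
#' @export
junction_observations <- function(pixels, labels = rep(NA_integer_, nrow(pixels)),
                                  source_image = NULL) {
  pixels <- as.matrix(pixels)
  stopifnot(ncol(pixels) == 2, length(labels) == nrow(pixels))
  lab <- labels[!is.na(labels)]
  if (anyDuplicated(lab)) stop("duplicate junction labels")
  structure(list(pixels = pixels, labels = as.integer(labels),
                 source_image = source_image),
            class = "junction_observations")
}

#' @export
print.junction_observations <- function(x, ...) {
  cat("<junction_observations> ", nrow(x$pixels), " points, ",
      sum(!is.na(x$labels)), " labeled\n", sep = "")
  invisible(x)
}
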