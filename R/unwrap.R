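#' Spherical parameterization of a closed mesh
#'
#' Longitude/latitude per face from the centroid directions: centroids
#' are translated to the mesh centroid, latitude is the angle to the
#' equatorial plane of `axis` and longitude the azimuth about `axis`
#' (measured from a reference direction orthogonal to the axis).
#' Faces whose centroid lies on the axis have undefined longitude and
#' are flagged.
#'
#' @param mesh a [surface_mesh()].
#' @param axis the long (rotation) axis of the heart, world frame
#'   (default +z).
#' @return An object of class `spherical_param`: per-face `lon` in
#'   `(-180, 180]`, `lat` in `[-90, 90]` degrees, unit `dirs`, and the
#'   `axis`/`center` used.
#' @export
spherical_parameterize <- function(mesh, axis = c(0, 0, 1)) {
  stopifnot(sum(axis^2) > 0)
  ax <- axis / sqrt(sum(axis^2))
  center <- colMeans(mesh$face_centroids)
  d <- sweep(mesh$face_centroids, 2, center)
  # orthonormal frame (e1, e2, ax)
  ref <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * ax) * ax
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(ax[2] * e1[3] - ax[3] * e1[2],
          ax[3] * e1[1] - ax[1] * e1[3],
          ax[1] * e1[2] - ax[2] * e1[1])
  x <- drop(d %*% e1); y <- drop(d %*% e2); z <- drop(d %*% ax)
  r <- sqrt(x^2 + y^2 + z^2)
  if (any(r < 1e-12)) stop("face centroid at the parameterization center")
  lat <- asin(pmax(-1, pmin(1, z / r))) * 180 / pi
  lon <- atan2(y, x) * 180 / pi
  on_axis <- sqrt(x^2 + y^2) < 1e-12 * pmax(r, 1)
  lon[on_axis] <- NA
  lon[!is.na(lon) & lon <= -180] <- lon[!is.na(lon) & lon <= -180] + 360
  dirs <- cbind(x, y, z) / r
  structure(list(lon = lon, lat = lat, dirs = dirs, axis = ax,
                 center = center, frame = rbind(e1, e2, ax)),
            class = "spherical_param")
}

# unit direction vectors in the parameterization frame for (lon, lat) deg
.lonlat_dirs <- function(lon, lat) {
  lo <- lon * pi / 180; la <- lat * pi / 180
  cbind(cos(la) * cos(lo), cos(la) * sin(lo), sin(la))
}

#' Forward Mercator projection of (lon, lat) degrees
#' @param lon,lat degrees.
#' @return matrix with columns `x` (degrees) and `y`.
#' @export
mercator_xy <- function(lon, lat) {
  cbind(x = lon, y = log(tan(pi / 4 + (lat * pi / 180) / 2)) * 180 / pi)
}

#' Forward Hammer projection of (lon, lat) degrees
#'
#' Standard equal-area Hammer projection (unit sphere scale).
#' @param lon,lat degrees.
#' @return matrix with columns `x` in `[-2 sqrt(2), 2 sqrt(2)]` and `y`
#'   in `[-sqrt(2), sqrt(2)]`.
#' @export
hammer_xy <- function(lon, lat) {
  lo <- lon * pi / 180; la <- lat * pi / 180
  den <- sqrt(1 + cos(la) * cos(lo / 2))
  cbind(x = 2 * sqrt(2) * cos(la) * sin(lo / 2) / den,
        y = sqrt(2) * sin(la) / den)
}

# inverse Hammer: (x, y) -> (lon, lat) degrees; NA outside the ellipse
.hammer_inverse <- function(x, y) {
  z2 <- 1 - (x / 4)^2 - (y / 2)^2
  ok <- z2 >= 0.5  # inside the projection ellipse
  z <- sqrt(pmax(z2, 0))
  lon <- 2 * atan2(z * x, 2 * (2 * z2 - 1)) * 180 / pi
  lat <- asin(pmax(-1, pmin(1, z * y))) * 180 / pi
  lon[!ok] <- NA; lat[!ok] <- NA
  list(lon = lon, lat = lat)
}

# nearest face on the sphere = max dot product with the face directions;
# chunked so the pixel x face similarity matrix stays small
.nearest_face_values <- function(param, values, lon, lat, chunk = 512) {
  n <- length(lon)
  out <- rep(NA_real_, n)
  tdirs <- t(param$dirs)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1, n)
    pd <- .lonlat_dirs(lon[s:e], lat[s:e])
    out[s:e] <- values[max.col(pd %*% tdirs, ties.method = "first")]
  }
  out
}

.rasterize_by_nearest <- function(param, values, lon_grid, lat_grid) {
  # raster rows = latitude (top row = max lat), cols = longitude
  gl <- expand.grid(lat = rev(lat_grid), lon = lon_grid)
  ok <- !is.na(gl$lon) & !is.na(gl$lat)
  vals <- rep(NA_real_, nrow(gl))
  if (any(ok))
    vals[ok] <- .nearest_face_values(param, values, gl$lon[ok], gl$lat[ok])
  matrix(vals, length(lat_grid), length(lon_grid))
}

#' Mercator raster of a per-face scalar map
#'
#' Cylindrical conformal unwrapping: `x = lon`,
#' `y = ln tan(45 + lat/2)`. Latitudes are clamped to `+-max_lat`
#' (Mercator diverges at the poles); pixels whose latitude exceeds the
#' clamp, or that no face reaches, are missing. Each raster pixel takes
#' the value of the face whose direction is nearest on the sphere
#' (no interpolation), so isochronal discontinuities stay sharp.
#'
#' @param param a [spherical_parameterize()] result.
#' @param values per-face scalars (e.g. activation times).
#' @param resolution raster width in pixels (default 360, i.e. 1
#'   degree/px); height follows from the latitude clamp.
#' @param max_lat latitude clamp in degrees (default 85).
#' @return An object of class `raster2d` with `grid` (matrix, top row =
#'   north), `projection = "mercator"`, and the pixel-to-lon/lat mapping
#'   in `lon_grid`/`lat_grid`.
#' @export
project_mercator <- function(param, values, resolution = 360,
                             max_lat = 85) {
  lon_grid <- seq(-180, 180, length.out = resolution + 1)[-1] -
    180 / resolution
  ymax <- log(tan(pi / 4 + (max_lat * pi / 180) / 2)) * 180 / pi
  px <- 360 / resolution
  y_grid <- seq(-ymax, ymax, by = px)
  lat_grid <- (2 * atan(exp(y_grid * pi / 180)) - pi / 2) * 180 / pi
  grid <- .rasterize_by_nearest(param, values, lon_grid, lat_grid)
  structure(list(grid = grid, projection = "mercator",
                 lon_grid = lon_grid, lat_grid = lat_grid,
                 y_grid = y_grid, max_lat = max_lat),
            class = "raster2d")
}

#' Hammer raster of a per-face scalar map
#'
#' Equal-area pseudo-azimuthal unwrapping on a regular `(x, y)` grid;
#' pixels are inverse-mapped to `(lon, lat)` (missing outside the
#' projection ellipse) and take the nearest face's value on the sphere.
#'
#' @param param a [spherical_parameterize()] result.
#' @param values per-face scalars.
#' @param resolution raster width in pixels (default 360; height is
#'   half).
#' @return An object of class `raster2d` with `grid`,
#'   `projection = "hammer"`, and the pixel `x_grid`/`y_grid`.
#' @export
project_hammer <- function(param, values, resolution = 360) {
  x_grid <- seq(-2 * sqrt(2), 2 * sqrt(2), length.out = resolution)
  y_grid <- seq(sqrt(2), -sqrt(2), length.out = ceiling(resolution / 2))
  gxy <- expand.grid(y = y_grid, x = x_grid)
  ll <- .hammer_inverse(gxy$x, gxy$y)
  ok <- !is.na(ll$lon)
  vals <- rep(NA_real_, nrow(gxy))
  if (any(ok))
    vals[ok] <- .nearest_face_values(param, values, ll$lon[ok], ll$lat[ok])
  structure(list(grid = matrix(vals, length(y_grid), length(x_grid)),
                 projection = "hammer", x_grid = x_grid, y_grid = y_grid),
            class = "raster2d")
}

#' @export
print.raster2d <- function(x, ...) {
  cat("<raster2d ", x$projection, "> ", nrow(x$grid), " x ", ncol(x$grid),
      " (", sum(!is.na(x$grid)), " non-missing)\n", sep = "")
  invisible(x)
}

#' Write a raster to CSV (grid) plus a YAML sidecar with the projection
#' parameters needed to invert pixels back to (lon, lat)
#'
#' @param raster a `raster2d`.
#' @param path CSV path; the sidecar gets extension `.yaml`.
#' @export
write_raster_csv <- function(raster, path) {
  utils::write.table(raster$grid, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "")
  meta <- raster[setdiff(names(raster), "grid")]
  meta <- lapply(meta, function(v) if (is.numeric(v)) as.numeric(v) else v)
  yaml::write_yaml(meta, paste0(tools::file_path_sans_ext(path), ".yaml"))
  invisible(path)
}

#' Render a raster to PNG with a simple color map
#'
#' @param raster a `raster2d`.
#' @param path PNG path.
#' @param palette color palette function (default [grDevices::hcl.colors]
#'   viridis).
#' @export
write_raster_png <- function(raster, path,
                             palette = function(n)
                               grDevices::hcl.colors(n, "viridis")) {
  g <- raster$grid
  rng <- range(g, na.rm = TRUE)
  n <- 256
  idx <- if (diff(rng) > 0) {
    pmin(n, pmax(1, 1 + floor((g - rng[1]) / diff(rng) * (n - 1))))
  } else matrix(1, nrow(g), ncol(g))
  cols <- grDevices::col2rgb(palette(n)) / 255
  img <- array(0, c(nrow(g), ncol(g), 3))
  for (ch in 1:3) {
    v <- matrix(0, nrow(g), ncol(g))
    v[!is.na(g)] <- cols[ch, idx[!is.na(g)]]
    img[, , ch] <- v
  }
  grDevices::png(path, width = ncol(g), height = nrow(g))
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::rasterImage(img, 0, 0, 1, 1, interpolate = FALSE)
  grDevices::dev.off()
  invisible(path)
}
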