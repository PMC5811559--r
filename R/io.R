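#' Read an image stack from a multi-page TIFF or a directory
#'
#' Directories are read in lexicographic file order. All pages/files must
#' share one shape. Values are returned as stored (`as.is`), so integer
#' images round-trip bit-exactly.
#'
#' @param path a `.tif`/`.tiff` file or a directory of them.
#' @return `list(frames = H x W x T array, n = T, source = path)`.
#' @export
read_image_stack <- function(path) {
  read_pages <- function(f) {
    pages <- tiff::readTIFF(f, all = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    lapply(pages, function(p) {
      bits <- attr(p, "bits.per.sample") %||% 8
      # 8/16-bit integer samples are normalized by readTIFF; rescale.
      # 32-bit samples are floating point and pass through unchanged.
      if (bits %in% c(8L, 16L)) round(p * (2^bits - 1)) else p
    })
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (length(files) == 0) stop("no TIFF files in directory: ", path)
    pages <- unlist(lapply(files, read_pages), recursive = FALSE)
  } else {
    if (!file.exists(path)) stop("path does not exist: ", path)
    pages <- read_pages(path)
  }
  shp <- dim(pages[[1]])
  for (p in pages)
    if (!identical(dim(p), shp))
      stop("mixed frame shapes in image stack: ", path)
  frames <- array(0, c(shp[1], shp[2], length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- pages[[i]]
  list(frames = frames, n = length(pages), source = path)
}

#' Write an image stack as a multi-page TIFF
#'
#' Integer-valued arrays are written as 16-bit integer TIFF (bit-exact
#' round trip); other arrays are scaled to `[0, 1]` floats only if
#' `normalize = TRUE`, else written as 32-bit float.
#'
#' @param frames H x W x T array (or H x W matrix).
#' @param path output `.tiff` path.
#' @param bits 16 (integer) or 32 (float); default chosen from the data.
#' @export
write_image_stack <- function(frames, path, bits = NULL) {
  if (length(dim(frames)) == 2) frames <- array(frames, c(dim(frames), 1))
  pages <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  int_data <- all(frames == round(frames)) && min(frames) >= 0 &&
    max(frames) < 65536
  if (is.null(bits)) bits <- if (int_data) 16L else 32L
  if (bits == 16L) {
    if (!int_data)
      stop("16-bit integer TIFF requires integer values in [0, 65535]")
    pages <- lapply(pages, function(p) p / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  } else {
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  }
  invisible(path)
}

#' Write a surface mesh to PLY, OBJ or STL
#'
#' ASCII, standard-conformant. PLY can carry one per-face scalar as a
#' float `quality` property; OBJ and STL cannot (a warning is issued and
#' geometry alone is written).
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @param format `"ply"`, `"obj"` or `"stl"`; default from the file
#'   extension.
#' @param face_scalars optional numeric per-face values (PLY only).
#' @export
write_surface <- function(mesh, path, format = NULL, face_scalars = NULL) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  if (!format %in% c("ply", "obj", "stl"))
    stop("unsupported format '", format, "'; supported: ply, obj, stl")
  v <- mesh$vertices; f <- mesh$faces
  if (!is.null(face_scalars) && format != "ply") {
    warning("per-face scalars are only supported by PLY; writing geometry only")
    face_scalars <- NULL
  }
  con <- file(path, "w")
  on.exit(close(con))
  fmt_num <- function(x) sprintf("%.9g", x)
  if (format == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 "comment panomap surface mesh",
                 paste("element vertex", nrow(v)),
                 "property float x", "property float y", "property float z",
                 paste("element face", nrow(f)),
                 "property list uchar int vertex_indices",
                 if (!is.null(face_scalars)) "property float quality",
                 "end_header"), con)
    writeLines(paste(fmt_num(v[, 1]), fmt_num(v[, 2]), fmt_num(v[, 3])), con)
    fl <- paste(3, f[, 1] - 1, f[, 2] - 1, f[, 3] - 1)
    if (!is.null(face_scalars)) {
      stopifnot(length(face_scalars) == nrow(f))
      fl <- paste(fl, fmt_num(face_scalars))
    }
    writeLines(fl, con)
  } else if (format == "obj") {
    writeLines(paste("v", fmt_num(v[, 1]), fmt_num(v[, 2]), fmt_num(v[, 3])),
               con)
    writeLines(paste("f", f[, 1], f[, 2], f[, 3]), con)
  } else {
    fr <- compute_face_frames(mesh)
    writeLines("solid panomap", con)
    for (i in seq_len(nrow(f))) {
      n <- fr$normals[i, ]
      writeLines(c(paste("facet normal", fmt_num(n[1]), fmt_num(n[2]),
                         fmt_num(n[3])),
                   "  outer loop",
                   paste("    vertex", fmt_num(v[f[i, 1], 1]),
                         fmt_num(v[f[i, 1], 2]), fmt_num(v[f[i, 1], 3])),
                   paste("    vertex", fmt_num(v[f[i, 2], 1]),
                         fmt_num(v[f[i, 2], 2]), fmt_num(v[f[i, 2], 3])),
                   paste("    vertex", fmt_num(v[f[i, 3], 1]),
                         fmt_num(v[f[i, 3], 2]), fmt_num(v[f[i, 3], 3])),
                   "  endloop", "endfacet"), con)
    }
    writeLines("endsolid panomap", con)
  }
  invisible(path)
}

#' Read a surface mesh written by [write_surface()] (ASCII PLY or OBJ)
#'
#' @param path mesh path.
#' @return `list(mesh, face_scalars)`; `face_scalars` is `NULL` when the
#'   file carries none.
#' @export
read_surface <- function(path) {
  format <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  if (format == "ply") {
    endh <- which(lines == "end_header")[1]
    header <- lines[seq_len(endh)]
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex", header, value = TRUE)))
    nf <- as.integer(sub("element face ", "",
                         grep("^element face", header, value = TRUE)))
    has_quality <- any(grepl("property float quality", header))
    vl <- lines[(endh + 1):(endh + nv)]
    fl <- lines[(endh + nv + 1):(endh + nv + nf)]
    v <- matrix(as.numeric(unlist(strsplit(vl, " "))), nv, byrow = TRUE)[, 1:3]
    fparts <- strsplit(fl, " ")
    f <- t(vapply(fparts, function(p) as.integer(p[2:4]) + 1L, integer(3)))
    scal <- if (has_quality)
      vapply(fparts, function(p) as.numeric(p[5]), numeric(1)) else NULL
    list(mesh = surface_mesh(v, f), face_scalars = scal)
  } else if (format == "obj") {
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    v <- matrix(as.numeric(unlist(strsplit(sub("^v ", "", vl), " "))),
                length(vl), 3, byrow = TRUE)
    f <- matrix(as.integer(unlist(strsplit(sub("^f ", "", fl), " "))),
                length(fl), 3, byrow = TRUE)
    list(mesh = surface_mesh(v, f), face_scalars = NULL)
  } else stop("unsupported format '", format, "'; supported: ply, obj")
}

#' Export a per-face scalar map as CSV
#'
#' Columns `face_index`, `value` (NA for missing faces).
#' @param map a [scalar_surface_map()].
#' @param path CSV path.
#' @export
write_map_csv <- function(map, path) {
  utils::write.csv(data.frame(face_index = seq_along(map$values),
                              value = map$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Save / load an optical movie as a directory (TIFF + YAML metadata)
#'
#' @param movie an [optical_movie()].
#' @param dir output directory (created).
#' @rdname movie_io
#' @export
write_movie <- function(movie, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rng <- range(movie$frames)
  fr <- if (diff(rng) > 0) (movie$frames - rng[1]) / diff(rng)
        else movie$frames * 0
  write_image_stack(fr, file.path(dir, "frames.tiff"), bits = 32L)
  write_image_stack(movie$mask, file.path(dir, "mask.tiff"), bits = 16L)
  yaml::write_yaml(list(sampling_rate = movie$sampling_rate,
                        camera_id = movie$camera_id,
                        value_range = as.numeric(rng)),
                   file.path(dir, "movie.yaml"))
  invisible(dir)
}

#' @rdname movie_io
#' @export
read_movie <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "movie.yaml"))
  frames <- read_image_stack(file.path(dir, "frames.tiff"))$frames
  rng <- unlist(meta$value_range)
  frames <- frames * (rng[2] - rng[1]) + rng[1]
  mask <- read_image_stack(file.path(dir, "mask.tiff"))$frames[, , 1]
  optical_movie(frames, meta$sampling_rate, meta$camera_id, mask)
}
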