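#' Triangulated surface mesh
#'
#' @param vertices N_verts x 3 matrix of world coordinates.
#' @param faces N_cells x 3 integer matrix of vertex indices (1-based),
#'   consistently wound so face normals point outward.
#' @param compute_frames also compute per-face centroids and unit normals.
#' @return An object of class `surface_mesh` with `vertices`, `faces` and,
#'   if requested, `face_centroids` and `face_normals`.
#' @export
surface_mesh <- function(vertices, faces, compute_frames = TRUE) {
  vertices <- unname(as.matrix(vertices))
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3,
            min(faces) >= 1, max(faces) <= nrow(vertices))
  m <- structure(list(vertices = vertices, faces = faces,
                      face_centroids = NULL, face_normals = NULL),
                 class = "surface_mesh")
  if (compute_frames) {
    fr <- compute_face_frames(m)
    m$face_centroids <- fr$centroids
    m$face_normals <- fr$normals
  }
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh> ", nrow(x$vertices), " vertices, ",
      nrow(x$faces), " faces\n", sep = "")
  invisible(x)
}

#' Per-face centroids and outward unit normals
#'
#' Centroid = mean of the three vertices; normal = normalized cross
#' product of the edge vectors, with the winding of the face determining
#' orientation (outward for meshes from [extract_surface()]).
#'
#' @param mesh a [surface_mesh()].
#' @return `list(centroids, normals)`, each N_cells x 3.
#' @export
compute_face_frames <- function(mesh) {
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  centroids <- (v1 + v2 + v3) / 3
  e1 <- v2 - v1
  e2 <- v3 - v1
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  bad <- which(len < 1e-14)
  if (length(bad) > 0)
    stop("degenerate (zero-area) face(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  list(centroids = centroids, normals = n / len)
}

#' Per-face areas
#' @param mesh a [surface_mesh()].
#' @export
face_areas <- function(mesh) {
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sqrt(rowSums(n^2)) / 2
}

#' Signed enclosed volume of a closed mesh
#'
#' Divergence-theorem sum of tetrahedron volumes; positive for outward
#' winding.
#' @param mesh a [surface_mesh()].
#' @export
mesh_volume <- function(mesh) {
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  sum(v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) +
      v1[, 2] * (v2[, 3] * v3[, 1] - v2[, 1] * v3[, 3]) +
      v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
}

# unique undirected edges as a 2-column matrix
.mesh_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- e[, 1] * (max(e) + 1) + e[, 2]
  e[!duplicated(key), , drop = FALSE]
}

#' Euler characteristic V - E + F
#' @param mesh a [surface_mesh()].
#' @export
euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - nrow(.mesh_edges(mesh$faces)) + nrow(mesh$faces)
}

#' Is every edge shared by exactly two faces?
#' @param mesh a [surface_mesh()].
#' @export
is_watertight <- function(mesh) {
  e <- rbind(mesh$faces[, c(1, 2)], mesh$faces[, c(2, 3)],
             mesh$faces[, c(3, 1)])
  key <- pmin(e[, 1], e[, 2]) * (max(e) + 1) + pmax(e[, 1], e[, 2])
  all(tabulate(match(key, unique(key))) == 2)
}

# triangulation table for one tetrahedron: for each of the 16
# inside/outside sign patterns of its 4 vertices, the triangles as
# triples of crossing-edge indices (edges 1..6 = pairs 12,13,14,23,24,34)
.tet_edge_pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))

.tet_case_table <- local({
  edge_id <- function(a, b) {
    for (i in 1:6)
      if (all(sort(c(a, b)) == .tet_edge_pairs[i, ])) return(i)
  }
  tab <- vector("list", 16)
  for (code in 0:15) {
    bits <- as.logical(bitwAnd(code, c(1, 2, 4, 8)))
    ins <- which(bits); outs <- which(!bits)
    tris <- list()
    if (length(ins) == 1) {
      i <- ins
      tris <- list(c(edge_id(i, outs[1]), edge_id(i, outs[2]),
                     edge_id(i, outs[3])))
    } else if (length(ins) == 3) {
      o <- outs
      tris <- list(c(edge_id(o, ins[1]), edge_id(o, ins[2]),
                     edge_id(o, ins[3])))
    } else if (length(ins) == 2) {
      i <- ins[1]; j <- ins[2]; k <- outs[1]; l <- outs[2]
      ik <- edge_id(i, k); il <- edge_id(i, l)
      jk <- edge_id(j, k); jl <- edge_id(j, l)
      tris <- list(c(ik, il, jl), c(ik, jl, jk))
    }
    tab[[code + 1]] <- tris
  }
  tab
})

# Freudenthal subdivision of the unit cube into 6 tetrahedra sharing the
# main diagonal; cube corners numbered 0..7 as dx + 2 dy + 4 dz.
# Face diagonals are translation-consistent, so meshes are watertight.
.cube_tets <- rbind(c(0, 1, 3, 7), c(0, 1, 5, 7), c(0, 2, 3, 7),
                    c(0, 2, 6, 7), c(0, 4, 5, 7), c(0, 4, 6, 7)) + 1

#' Extract an isosurface mesh from an occupancy volume
#'
#' Marching tetrahedra over the finest-grid cell centers (each grid cube
#' is split into six Freudenthal tetrahedra; crossing edges are linearly
#' interpolated). Samples exactly equal to `iso` (the 0.5 boundary cells)
#' are treated as inside and internally offset to the midpoint between
#' `iso` and the inside value so that interpolation is non-degenerate;
#' the surface therefore passes between the boundary cells and their
#' outside neighbours. The mesh is watertight with consistent outward
#' winding (positive enclosed volume).
#'
#' @param volume an [occupancy_volume()], or a list with elements `field`
#'   (3D array), `origin`, `spacing` (3-vector per-axis sample spacing).
#' @param iso iso level (default 0.5).
#' @param antialias for occupancy volumes, average the `{0, 0.5, 1}`
#'   indicator over a 3^3 box before extraction (default `TRUE`). The
#'   smoothed indicator's `iso`-level tracks the hull boundary with far
#'   less voxel staircase bias than the raw three-valued field.
#' @return A [surface_mesh()].
#' @export
extract_surface <- function(volume, iso = 0.5, antialias = TRUE) {
  if (inherits(volume, "occupancy_volume")) {
    field <- volume$occupancy
    spacing <- volume$extent / dim(field)
    origin <- volume$origin + spacing / 2  # samples at cell centers
    if (antialias && !all(field == field[1])) {
      n <- dim(field)
      pad <- array(0, n + 2)
      pad[2:(n[1] + 1), 2:(n[2] + 1), 2:(n[3] + 1)] <- field
      sm <- array(0, n)
      for (di in 0:2) for (dj in 0:2) for (dk in 0:2)
        sm <- sm + pad[(1:n[1]) + di, (1:n[2]) + dj, (1:n[3]) + dk]
      field <- sm / 27
    }
  } else {
    field <- volume$field
    spacing <- rep(volume$spacing, length.out = 3)
    origin <- volume$origin
  }
  dims <- dim(field)
  fmax <- max(field)
  eqiso <- abs(field - iso) < 1e-12
  if (any(eqiso)) {
    if (fmax <= iso + 1e-12) field[eqiso] <- iso + 0.25 * abs(iso + 1e-3)
    else field[eqiso] <- (iso + fmax) / 2
  }
  inside <- field > iso
  if (all(inside) || !any(inside)) stop("no surface: field does not cross iso")

  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  # cubes with mixed corners
  cin <- array(0L, dims - 1)
  offs <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  for (cidx in 1:8) {
    cin <- cin + inside[(1:(nx - 1)) + offs[cidx, 1],
                        (1:(ny - 1)) + offs[cidx, 2],
                        (1:(nz - 1)) + offs[cidx, 3]]
  }
  mixed <- which(cin > 0L & cin < 8L)
  if (length(mixed) == 0) stop("no surface: field does not cross iso")
  mi <- arrayInd(mixed, dims - 1)

  # global sample ids for the 8 corners of each mixed cube
  gid <- matrix(0, length(mixed), 8)
  val <- matrix(0, length(mixed), 8)
  for (cidx in 1:8) {
    ii <- mi[, 1] + offs[cidx, 1]
    jj <- mi[, 2] + offs[cidx, 2]
    kk <- mi[, 3] + offs[cidx, 3]
    gid[, cidx] <- (ii - 1) + nx * ((jj - 1) + ny * (kk - 1))
    val[, cidx] <- field[cbind(ii, jj, kk)]
  }
  bin <- val > iso

  # accumulate triangles as edge-key triples
  tri_a <- list(); tri_b <- list(); tri_ref <- list()
  nt <- 0
  for (tt in 1:6) {
    corn <- .cube_tets[tt, ]
    b4 <- bin[, corn, drop = FALSE]
    code <- b4[, 1] + 2 * b4[, 2] + 4 * b4[, 3] + 8 * b4[, 4]
    for (cs in 0:15) {
      tris <- .tet_case_table[[cs + 1]]
      if (length(tris) == 0) next
      rows <- which(code == cs)
      if (length(rows) == 0) next
      ins_corn <- corn[as.logical(bitwAnd(cs, c(1, 2, 4, 8)))]
      # reference interior point: mean of inside corner samples
      refg <- gid[rows, ins_corn, drop = FALSE]
      for (tr in tris) {
        ga <- matrix(0, length(rows), 3)
        gb <- matrix(0, length(rows), 3)
        for (e in 1:3) {
          pr <- .tet_edge_pairs[tr[e], ]
          ga[, e] <- gid[rows, corn[pr[1]]]
          gb[, e] <- gid[rows, corn[pr[2]]]
        }
        nt <- nt + 1
        tri_a[[nt]] <- ga
        tri_b[[nt]] <- gb
        tri_ref[[nt]] <- refg
      }
    }
  }
  ga <- do.call(rbind, tri_a)
  gb <- do.call(rbind, tri_b)
  # edge keys (undirected)
  lo <- pmin(ga, gb); hi <- pmax(ga, gb)
  key <- lo * (as.double(nx) * ny * nz) + hi
  ukey <- sort(unique(as.vector(key)))
  fidx <- matrix(match(as.vector(key), ukey), nrow(key), 3)

  # vertex positions: interpolate along each unique crossing edge
  ulo <- ukey %/% (as.double(nx) * ny * nz)
  uhi <- ukey %% (as.double(nx) * ny * nz)
  pos_of <- function(g) {
    i <- g %% nx
    j <- (g %/% nx) %% ny
    k <- g %/% (nx * ny)
    cbind(origin[1] + i * spacing[1],
          origin[2] + j * spacing[2],
          origin[3] + k * spacing[3])
  }
  val_of <- function(g) field[1 + g %% nx +
                                nx * ((g %/% nx) %% ny) +
                                nx * ny * (g %/% (nx * ny))]
  vlo <- val_of(ulo); vhi <- val_of(uhi)
  tpar <- (iso - vlo) / (vhi - vlo)
  verts <- pos_of(ulo) * (1 - tpar) + pos_of(uhi) * tpar

  # consistent outward winding: normal away from the tet's inside corners
  refp <- matrix(0, nrow(fidx), 3)
  rstart <- 0
  for (b in seq_len(nt)) {
    rg <- tri_ref[[b]]
    rp <- pos_of(as.vector(rg))
    for (d in 1:3)
      refp[rstart + seq_len(nrow(rg)), d] <-
        rowMeans(matrix(rp[, d], nrow(rg), ncol(rg)))
    rstart <- rstart + nrow(rg)
  }
  v1 <- verts[fidx[, 1], , drop = FALSE]
  v2 <- verts[fidx[, 2], , drop = FALSE]
  v3 <- verts[fidx[, 3], , drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  outward <- rowSums(nrm * ((v1 + v2 + v3) / 3 - refp)) >= 0
  flip <- !outward
  tmp <- fidx[flip, 2]
  fidx[flip, 2] <- fidx[flip, 3]
  fidx[flip, 3] <- tmp
  surface_mesh(verts, fidx)
}

#' Taubin (shrink-compensated) mesh smoothing
#'
#' Alternating Laplacian steps with positive (`lam`) and negative (`mu`)
#' weights; `|mu| > lam` compensates the shrinkage of plain Laplacian
#' smoothing so the enclosed volume is approximately preserved.
#' Connectivity is unchanged.
#'
#' @param mesh a [surface_mesh()].
#' @param iterations number of lambda-mu passes (default 50).
#' @param lam positive smoothing factor (default 0.5).
#' @param mu negative un-shrinking factor (default -0.53).
#' @return Smoothed [surface_mesh()].
#' @export
smooth_surface <- function(mesh, iterations = 50, lam = 0.5, mu = -0.53) {
  if (iterations == 0) return(mesh)
  e <- .mesh_edges(mesh$faces)
  nv <- nrow(mesh$vertices)
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(nv, nv))
  deg <- Matrix::rowSums(A)
  W <- Matrix::Diagonal(x = 1 / deg) %*% A
  v <- mesh$vertices
  for (it in seq_len(iterations)) {
    v <- v + lam * (as.matrix(W %*% v) - v)
    v <- v + mu * (as.matrix(W %*% v) - v)
  }
  surface_mesh(v, mesh$faces)
}

#' Icosphere test mesh
#'
#' Subdivided icosahedron projected onto a sphere; watertight with
#' outward winding.
#'
#' @param subdivisions number of 4-to-1 subdivisions (default 3).
#' @param radius sphere radius.
#' @param center 3-vector center.
#' @export
icosphere <- function(subdivisions = 3, radius = 1, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nvv <- nrow(v)
    mid_cache <- new.env(hash = TRUE)
    midpoint <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[k]])) return(mid_cache[[k]])
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      mid_cache[[k]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc),
                  c(ab, bc, ca))
    }
    f <- nf
  }
  v <- sweep(v * radius, 2, center, `+`)
  surface_mesh(v, f)
}
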