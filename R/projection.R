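#' Classify mesh faces for one camera by normal angle
#'
#' For each face the angle between its outward normal `N_cell` and the
#' camera viewing direction `N_ic` is computed. Faces squarely toward the
#' camera have angles near 180 degrees. Angles below `low` are excluded
#' from assignment at this camera; angles in the closed band
#' `[low, high]` are edge cells; angles above `high` are assigned.
#'
#' @param mesh a [surface_mesh()] with unit face normals.
#' @param camera a [camera_model()].
#' @param low,high band thresholds in degrees (defaults 90 and 115).
#' @return Character vector per face: `"excluded"`, `"edge"` or
#'   `"assigned"`.
#' @export
classify_faces <- function(mesh, camera, low = 90, high = 115) {
  nic <- camera_normal(camera)
  ct <- pmin(1, pmax(-1, drop(mesh$face_normals %*% nic)))
  theta <- acos(ct) * 180 / pi
  eps <- 1e-7   # keep the closed [low, high] band stable to round-off
  out <- rep("excluded", length(theta))
  out[theta >= low - eps & theta <= high + eps] <- "edge"
  out[theta > high + eps] <- "assigned"
  out
}

#' Project face centroids onto a camera
#'
#' Each centroid is projected with [project_point()] and rounded to the
#' nearest integer pixel. Centroids behind the camera or outside the
#' frame are marked invalid (NA).
#'
#' @param mesh a [surface_mesh()].
#' @param camera a calibrated [camera_model()] with a known `image_size`.
#' @return N_cells x 2 integer matrix of `(u, v)` pixels with NA rows for
#'   invalid projections.
#' @export
project_centroids <- function(mesh, camera) {
  uv <- project_point(camera, mesh$face_centroids, allow_behind = TRUE)
  px <- round(uv)
  if (!any(is.na(camera$image_size))) {
    bad <- !is.finite(px[, 1]) |
      px[, 1] < 0 | px[, 1] > camera$image_size[1] - 1 |
      px[, 2] < 0 | px[, 2] > camera$image_size[2] - 1
    px[bad, ] <- NA
  }
  colnames(px) <- c("u", "v")
  px
}

#' Project conditioned camera movies onto the mesh
#'
#' Texture mapping with angle-classified camera assignment: per camera,
#' faces are classified with [classify_faces()] and centroids projected
#' with [project_centroids()]. A face assigned by exactly one camera takes
#' that camera's closest-pixel trace; a face assigned by several cameras
#' (overlap) takes the weighted average `sum(w_i s_i) / sum(w_i)` with
#' `w_i` the weighted-gradient-mask value at the projected pixel; an edge
#' face (no assigning camera, at least one edge camera) takes the same
#' weighted average over every camera classifying it edge or assigned.
#' Faces excluded by all cameras carry missing signal. Cameras whose
#' projected pixel is invalid, background, or has zero weight do not
#' contribute.
#'
#' @param mesh a [surface_mesh()].
#' @param movies named list of [optical_movie()] per camera.
#' @param weight_masks named list of [build_weight_mask()] results, same
#'   names.
#' @param cameras named list of [camera_model()], same names.
#' @param low,high classification thresholds, degrees.
#' @return An object of class `projected_dataset`: `mesh`, `signals`
#'   (N_cells x T, NA rows = missing), `class` (per-face global class:
#'   excluded/edge/assigned/overlap), `assignments` (per-face list of
#'   contributing cameras, pixels and weights), `sampling_rate`.
#' @export
assemble_projected_signals <- function(mesh, movies, weight_masks, cameras,
                                       low = 90, high = 115) {
  ids <- names(cameras)
  stopifnot(length(ids) >= 1, !is.null(ids),
            setequal(ids, names(movies)), setequal(ids, names(weight_masks)))
  Tn <- unique(vapply(movies, function(m) dim(m$frames)[3], numeric(1)))
  if (length(Tn) != 1) stop("length mismatch: movies differ in frame count")
  fs <- unique(vapply(movies, function(m) m$sampling_rate, numeric(1)))
  if (length(fs) != 1) stop("length mismatch: movies differ in sampling rate")
  nf <- nrow(mesh$faces)

  klass <- matrix("excluded", nf, length(ids), dimnames = list(NULL, ids))
  wt <- matrix(0, nf, length(ids), dimnames = list(NULL, ids))
  pix <- vector("list", length(ids)); names(pix) <- ids
  for (id in ids) {
    kl <- classify_faces(mesh, cameras[[id]], low, high)
    px <- project_centroids(mesh, cameras[[id]])
    mv <- movies[[id]]
    w <- rep(0, nf)
    ok <- kl != "excluded" & is.finite(px[, 1])
    if (any(ok)) {
      row <- px[ok, 2] + 1
      col <- px[ok, 1] + 1
      inb <- row >= 1 & row <= nrow(mv$mask) & col >= 1 & col <= ncol(mv$mask)
      idx <- cbind(row, col)
      wv <- rep(0, sum(ok))
      wv[inb] <- weight_masks[[id]]$weights[idx[inb, , drop = FALSE]] *
        (mv$mask[idx[inb, , drop = FALSE]] == 1)
      w[ok] <- wv
    }
    kl[w == 0] <- "excluded"   # unusable pixel: no contribution
    klass[, id] <- kl
    wt[, id] <- w
    pix[[id]] <- px
  }

  n_assigned <- rowSums(klass == "assigned")
  n_edge <- rowSums(klass == "edge")
  global <- rep("excluded", nf)
  global[n_assigned == 1] <- "assigned"
  global[n_assigned >= 2] <- "overlap"
  global[n_assigned == 0 & n_edge > 0] <- "edge"

  # per-camera trace lookup for needed faces
  signals <- matrix(NA_real_, nf, Tn)
  wsum <- rep(0, nf)
  acc <- matrix(0, nf, Tn)
  for (id in ids) {
    contrib <- (global %in% c("assigned", "overlap") & klass[, id] == "assigned") |
      (global == "edge" & klass[, id] %in% c("edge", "assigned"))
    if (!any(contrib)) next
    mv <- movies[[id]]
    M <- .movie_mat(mv)
    px <- pix[[id]][contrib, , drop = FALSE]
    lin <- (px[, 2] + 1) + nrow(mv$mask) * px[, 1]
    w <- wt[contrib, id]
    acc[contrib, ] <- acc[contrib, , drop = FALSE] + w * M[lin, , drop = FALSE]
    wsum[contrib] <- wsum[contrib] + w
  }
  has <- wsum > 0
  signals[has, ] <- acc[has, , drop = FALSE] / wsum[has]
  global[!has] <- "excluded"

  assignments <- lapply(seq_len(nf), function(i) {
    contrib_ids <- ids[(global[i] %in% c("assigned", "overlap") &
                          klass[i, ] == "assigned") |
                         (global[i] == "edge" &
                            klass[i, ] %in% c("edge", "assigned"))]
    if (global[i] == "excluded") contrib_ids <- character(0)
    list(face_index = i, klass = global[i],
         cameras = lapply(contrib_ids, function(id)
           list(camera_id = id, pixel = pix[[id]][i, ],
                weight = wt[i, id])))
  })
  structure(list(mesh = mesh, signals = signals, class = global,
                 per_camera_class = klass, assignments = assignments,
                 sampling_rate = fs),
            class = "projected_dataset")
}

#' @export
print.projected_dataset <- function(x, ...) {
  cat("<projected_dataset> ", nrow(x$signals), " faces x ",
      ncol(x$signals), " samples @ ", x$sampling_rate, " Hz\n", sep = "")
  tb <- table(x$class)
  cat("  classes:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
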