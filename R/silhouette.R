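#' Segment the heart silhouette in a rotation image
#'
#' Thresholds a grayscale image into a binary heart mask. By default Otsu's
#' method picks the threshold and the heart is assumed darker than the
#' backdrop (the rig images the heart against a contrast backdrop);
#' `dark_object = FALSE` flips the polarity. Polygon edits are applied
#' after thresholding, in order, to add or remove regions the threshold
#' misclassifies. Interior holes are filled (the silhouette must be simply
#' connected for carving) and only the largest connected component is
#' kept.
#'
#' @param image numeric matrix `[row, col]`; any finite range.
#' @param threshold optional threshold in the image's value range; `NULL`
#'   uses Otsu's method.
#' @param polygon_edits optional list of `list(polygon = <n x 2 (u, v)
#'   matrix>, action = "add"|"remove")` applied in order.
#' @param dark_object is the heart darker than the backdrop?
#' @param fill_holes fill interior holes after thresholding.
#' @return Binary matrix (0/1), same shape; 1 = heart.
#' @export
segment_silhouette <- function(image, threshold = NULL, polygon_edits = NULL,
                               dark_object = TRUE, fill_holes = TRUE) {
  img <- as.matrix(image)
  stopifnot(all(is.finite(img)))
  rng <- range(img)
  if (is.null(threshold)) {
    scaled <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
    th01 <- EBImage::otsu(scaled, range = c(0, 1))
    threshold <- rng[1] + th01 * diff(rng)
  }
  mask <- if (dark_object) (img < threshold) else (img > threshold)
  mask <- mask * 1
  if (!is.null(polygon_edits)) {
    for (ed in polygon_edits) {
      inside <- .points_in_polygon_mask(dim(img), ed$polygon)
      if (identical(ed$action, "add")) mask[inside] <- 1
      else if (identical(ed$action, "remove")) mask[inside] <- 0
      else stop("unknown polygon edit action: ", ed$action)
    }
  }
  if (fill_holes && any(mask > 0)) mask <- EBImage::fillHull(mask)
  if (!any(mask > 0)) stop("empty silhouette: no foreground after thresholding")
  lab <- EBImage::bwlabel(mask)
  tab <- tabulate(lab[lab > 0])
  mask <- (lab == which.max(tab)) * 1
  mask
}

# logical matrix of pixels whose (u, v) centers fall inside the polygon
.points_in_polygon_mask <- function(shape, polygon) {
  polygon <- as.matrix(polygon)
  out <- matrix(FALSE, shape[1], shape[2])
  if (nrow(polygon) < 3) return(out)
  uu <- rep(seq_len(shape[2]) - 1, each = shape[1])
  vv <- rep(seq_len(shape[1]) - 1, times = shape[2])
  inside <- mgcv::in.out(rbind(polygon, polygon[1, ]), cbind(uu, vv))
  out[] <- inside
  out
}

#' Assemble segmented masks into a silhouette stack
#'
#' Bundles per-angle binary masks with their rotation angles, the geometry
#' camera and the rotation axis. The standard acquisition images the heart
#' every 5 degrees over a full revolution (72 masks).
#'
#' @param masks list of binary matrices, all the same shape.
#' @param start_angle,step first angle and angular increment, degrees.
#' @param camera the geometry [camera_model()].
#' @param axis unit 3-vector of the rotation axis in the world frame
#'   (default world +z).
#' @param axis_point a point on the axis (default origin).
#' @param angles explicit angle vector overriding `start_angle`/`step`.
#' @return An object of class `silhouette_stack`.
#' @export
assemble_stack <- function(masks, start_angle = 0, step = 5, camera,
                           axis = c(0, 0, 1), axis_point = c(0, 0, 0),
                           angles = NULL) {
  stopifnot(length(masks) >= 1)
  shp <- dim(masks[[1]])
  for (m in masks)
    if (!identical(dim(m), shp))
      stop("inconsistent stack: masks differ in shape")
  if (is.null(angles)) {
    stopifnot(step > 0)
    angles <- start_angle + (seq_along(masks) - 1) * step
  }
  stopifnot(length(angles) == length(masks))
  if (any(diff(angles) <= 0)) stop("inconsistent stack: angles must increase")
  if (max(angles) - min(angles) >= 360)
    stop("inconsistent stack: angles span >= 360 degrees")
  masks <- lapply(masks, function(m) {
    m <- as.matrix(m) * 1
    if (!all(m %in% c(0, 1))) stop("inconsistent stack: masks must be binary")
    m
  })
  structure(list(masks = masks, angles = as.numeric(angles), camera = camera,
                 axis = axis / sqrt(sum(axis^2)),
                 axis_point = as.numeric(axis_point)),
            class = "silhouette_stack")
}

#' @export
print.silhouette_stack <- function(x, ...) {
  cat("<silhouette_stack> ", length(x$masks), " masks of ",
      paste(dim(x$masks[[1]]), collapse = " x "), ", angles ",
      min(x$angles), "..", max(x$angles), " deg\n", sep = "")
  invisible(x)
}
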