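#' Per-camera optical mapping movie
#'
#' @param frames H x W x T numeric array of fluorescence intensity.
#' @param sampling_rate frames per second, Hz.
#' @param camera_id camera identifier (e.g. `"A"`, `"B"`, `"C"`, `"D"`).
#' @param mask binary H x W foreground mask (1 = pixel carries
#'   physiological signal); default all foreground.
#' @return An object of class `optical_movie`.
#' @export
optical_movie <- function(frames, sampling_rate, camera_id = "A",
                          mask = NULL) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] >= 2,
            sampling_rate > 0)
  if (is.null(mask)) mask <- matrix(1, dim(frames)[1], dim(frames)[2])
  mask <- as.matrix(mask) * 1
  stopifnot(all(dim(mask) == dim(frames)[1:2]))
  structure(list(frames = frames, sampling_rate = sampling_rate,
                 camera_id = camera_id, mask = mask),
            class = "optical_movie")
}

#' @export
print.optical_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat("<optical_movie ", x$camera_id, "> ", d[1], " x ", d[2], " x ", d[3],
      " @ ", x$sampling_rate, " Hz, ", sum(x$mask == 1),
      " foreground pixels\n", sep = "")
  invisible(x)
}

# frames as a (H*W) x T matrix and back
.movie_mat <- function(movie) matrix(movie$frames, ncol = dim(movie$frames)[3])
.mat_movie <- function(movie, M) {
  movie$frames <- array(M, dim(movie$frames))
  movie
}

#' Normalize optical action potentials to [0, 1]
#'
#' Per-pixel min-max normalization over time on foreground pixels;
#' background pixels are zeroed. Foreground pixels with a constant trace
#' carry no signal: they are moved to background with a warning.
#'
#' @param movie an [optical_movie()].
#' @return Normalized [optical_movie()].
#' @export
normalize_traces <- function(movie) {
  M <- .movie_mat(movie)
  fg <- which(movie$mask == 1)
  mn <- apply(M[fg, , drop = FALSE], 1, min)
  mx <- apply(M[fg, , drop = FALSE], 1, max)
  flat <- mx - mn <= 0
  if (any(flat)) {
    warning(sum(flat), " foreground pixel(s) with constant traces moved to background")
    movie$mask[fg[flat]] <- 0
    fg <- fg[!flat]
    mn <- mn[!flat]; mx <- mx[!flat]
  }
  out <- matrix(0, nrow(M), ncol(M))
  out[fg, ] <- (M[fg, , drop = FALSE] - mn) / (mx - mn)
  .mat_movie(movie, out)
}

#' Spatial binning with a box-averaging kernel
#'
#' Per-frame mean over a `kernel x kernel` window restricted to
#' foreground pixels, so background never contaminates the average. The
#' mask is unchanged.
#'
#' @param movie an [optical_movie()].
#' @param kernel odd window size (default 3).
#' @return Binned [optical_movie()].
#' @export
spatial_bin <- function(movie, kernel = 3) {
  stopifnot(kernel >= 1, kernel %% 2 == 1)
  if (kernel == 1) return(movie)
  box <- matrix(1, kernel, kernel)
  den <- EBImage::filter2(movie$mask, box, boundary = 0)
  den[den < 0.5] <- NA  # no foreground in window
  fgm <- movie$mask == 1
  T_ <- dim(movie$frames)[3]
  out <- movie$frames
  for (t in seq_len(T_)) {
    num <- EBImage::filter2(movie$frames[, , t] * movie$mask, box,
                            boundary = 0)
    fr <- num / round(den)
    fr[!fgm] <- 0
    fr[is.na(fr)] <- 0
    out[, , t] <- fr
  }
  movie$frames <- out
  movie
}

#' Design the temporal FIR low-pass filter taps
#'
#' Hamming-windowed sinc low-pass (the 0 Hz lower band edge makes the
#' band pass degenerate) with unit DC gain.
#'
#' @param order filter order (must be even; `order + 1` taps).
#' @param high upper passband edge, Hz.
#' @param sampling_rate Hz.
#' @return Numeric vector of `order + 1` taps.
#' @export
design_temporal_filter <- function(order = 100, high = 100,
                                   sampling_rate = 1000) {
  if (sampling_rate <= 2 * high)
    stop("sampling rate too low: need sampling_rate > 2 * upper band edge")
  stopifnot(order >= 2, order %% 2 == 0)
  taps <- as.numeric(signal::fir1(order, high / (sampling_rate / 2),
                                  type = "low"))
  taps / sum(taps)   # exact unit DC gain
}

#' Temporal FIR filtering of every foreground trace
#'
#' Applies the linear-phase FIR low-pass from
#' [design_temporal_filter()] along time. Traces are edge-padded, the
#' filter's group delay (`order / 2` samples) is compensated, so features
#' are not shifted; DC gain is 1.
#'
#' @param movie an [optical_movie()].
#' @param order filter order (default 100).
#' @param passband `(low, high)` band edges in Hz; the low edge must be 0
#'   (default `c(0, 100)`).
#' @return Filtered [optical_movie()].
#' @export
filter_temporal <- function(movie, order = 100, passband = c(0, 100)) {
  if (passband[1] != 0)
    stop("only a 0 Hz lower band edge is supported (low-pass)")
  taps <- design_temporal_filter(order, passband[2], movie$sampling_rate)
  M <- .movie_mat(movie)
  fg <- which(movie$mask == 1)
  Tn <- ncol(M)
  L <- order / 2
  # edge-replicate pad, filter by FFT convolution, drop the group delay
  X <- cbind(matrix(M[fg, 1], length(fg), order),
             M[fg, , drop = FALSE],
             matrix(M[fg, Tn], length(fg), order))
  N <- stats::nextn(Tn + 3 * order + 1)
  X <- cbind(X, matrix(0, length(fg), N - ncol(X)))
  Hf <- stats::fft(c(taps, rep(0, N - length(taps))))
  Y <- t(Re(stats::mvfft(stats::mvfft(t(X)) * Hf, inverse = TRUE))) / N
  out <- matrix(0, nrow(M), Tn)
  out[fg, ] <- Y[, (order + L + 1):(order + L + Tn), drop = FALSE]
  .mat_movie(movie, out)
}

#' First-order drift removal
#'
#' Subtracts the least-squares line from every foreground trace and
#' re-adds the trace mean, so only the linear drift component is removed.
#'
#' @param movie an [optical_movie()].
#' @return Detrended [optical_movie()].
#' @export
remove_drift <- function(movie) {
  M <- .movie_mat(movie)
  fg <- which(movie$mask == 1)
  Tn <- ncol(M)
  tc <- seq_len(Tn) - (Tn + 1) / 2
  slope <- (M[fg, , drop = FALSE] %*% tc) / sum(tc^2)
  M[fg, ] <- M[fg, , drop = FALSE] - slope %*% t(tc)
  .mat_movie(movie, M)
}

# does the closed polygon self-intersect (proper crossings only)?
.polygon_simple <- function(poly) {
  n <- nrow(poly)
  if (n < 4) return(TRUE)
  seg <- cbind(poly, poly[c(2:n, 1), ])
  cross2 <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) -
    (a[2] - o[2]) * (b[1] - o[1])
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (j == i + 1 || (i == 1 && j == n)) next
    p1 <- seg[i, 1:2]; p2 <- seg[i, 3:4]
    q1 <- seg[j, 1:2]; q2 <- seg[j, 3:4]
    d1 <- cross2(q1, q2, p1); d2 <- cross2(q1, q2, p2)
    d3 <- cross2(p1, p2, q1); d4 <- cross2(p1, p2, q2)
    if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
        ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(FALSE)
  }
  TRUE
}

.polygon_area <- function(poly) {
  n <- nrow(poly)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Remove a polygonal region from the movie foreground
#'
#' Marks foreground pixels whose centers fall inside the polygon as
#' background and zeroes their traces; used e.g. to strip the atria when
#' only the ventricles are analyzed. Degenerate (zero-area) polygons are
#' a no-op; self-intersecting polygons are rejected.
#'
#' @param movie an [optical_movie()].
#' @param polygon n x 2 matrix of `(u, v)` vertices.
#' @return An [optical_movie()] with the region removed.
#' @export
mask_region <- function(movie, polygon) {
  polygon <- as.matrix(polygon)
  if (!.polygon_simple(polygon)) stop("invalid polygon: self-intersecting")
  if (nrow(polygon) < 3 || .polygon_area(polygon) == 0) return(movie)
  inside <- .points_in_polygon_mask(dim(movie$mask), polygon)
  rm_px <- inside & movie$mask == 1
  movie$mask[rm_px] <- 0
  M <- .movie_mat(movie)
  M[which(rm_px), ] <- 0
  .mat_movie(movie, M)
}

#' Weighted gradient mask for camera blending
#'
#' Surface curvature toward the silhouette edge of each camera's view
#' degrades signal-to-noise, so edge pixels are down-weighted when
#' cameras are blended: center (deepest) pixels get weight 1 and the
#' outermost foreground pixels get exactly 0.5, linear in the normalized
#' distance-to-background `w = 0.5 + 0.5 (d - d_min) / (d_max - d_min)`.
#' Background pixels get 0. A mask whose foreground all sits at one depth
#' (e.g. a single pixel) gets weight 1.
#'
#' @param mask binary H x W matrix with at least one foreground pixel.
#' @return An object of class `weight_mask` wrapping the H x W `weights`
#'   matrix.
#' @export
build_weight_mask <- function(mask) {
  mask <- as.matrix(mask) * 1
  if (!any(mask == 1)) stop("empty mask: no foreground pixels")
  # pad so foreground touching the image border still counts as edge
  padded <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
  padded[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  d <- as.matrix(EBImage::distmap(padded, metric = "euclidean"))
  d <- d[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)]
  fg <- mask == 1
  dmin <- min(d[fg]); dmax <- max(d[fg])
  w <- matrix(0, nrow(mask), ncol(mask))
  w[fg] <- if (dmax > dmin) 0.5 + 0.5 * (d[fg] - dmin) / (dmax - dmin) else 1
  structure(list(weights = w), class = "weight_mask")
}

#' Full conditioning pipeline for one camera movie
#'
#' Normalize, spatially bin, temporally filter and detrend, in that
#' order (`normalize_first = FALSE` filters before normalizing).
#'
#' @param movie an [optical_movie()].
#' @param kernel spatial binning window (odd; default 3).
#' @param order FIR filter order (default 100).
#' @param passband FIR band edges in Hz (default `c(0, 100)`).
#' @param detrend apply first-order drift removal (default `TRUE`).
#' @param normalize_first normalize before filtering (default `TRUE`).
#' @param polygons optional list of polygons removed from the foreground
#'   before conditioning.
#' @return Conditioned [optical_movie()].
#' @export
condition_movie <- function(movie, kernel = 3, order = 100,
                            passband = c(0, 100), detrend = TRUE,
                            normalize_first = TRUE, polygons = NULL) {
  for (poly in polygons) movie <- mask_region(movie, poly)
  if (normalize_first) movie <- normalize_traces(movie)
  movie <- spatial_bin(movie, kernel)
  movie <- filter_temporal(movie, order, passband)
  movie <- remove_drift(movie)
  if (!normalize_first) movie <- normalize_traces(movie)
  movie
}
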