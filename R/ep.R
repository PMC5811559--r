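#' Per-face scalar surface map
#'
#' @param values numeric vector, one scalar per face (NA = missing).
#' @param kind `"activation"`, `"apd"` or `"df"`.
#' @param mesh the [surface_mesh()] the values live on (optional).
#' @param units unit string (ms, Hz, ...).
#' @export
scalar_surface_map <- function(values, kind, mesh = NULL, units = "") {
  structure(list(values = as.numeric(values), kind = kind, mesh = mesh,
                 units = units),
            class = "scalar_surface_map")
}

#' @export
print.scalar_surface_map <- function(x, ...) {
  cat("<scalar_surface_map ", x$kind, "> ", length(x$values), " faces, ",
      sum(is.na(x$values)), " missing",
      if (nzchar(x$units)) paste0(", units ", x$units), "\n", sep = "")
  invisible(x)
}

# sub-sample refinement of a discrete argmax by parabolic interpolation
.parabolic_peak <- function(y, k) {
  if (k <= 1 || k >= length(y)) return(k)
  # a quadratic fit is meaningless on a delta-like peak (step upstroke)
  if (min(y[k - 1], y[k + 1]) < 0.1 * y[k]) return(k)
  denom <- y[k - 1] - 2 * y[k] + y[k + 1]
  if (abs(denom) < 1e-12) return(k)
  off <- 0.5 * (y[k - 1] - y[k + 1]) / denom
  k + max(-0.5, min(0.5, off))
}

# index of the maximum; ties broken to the center of the maximal run
.argmax_center <- function(y) {
  mx <- max(y)
  idx <- which(y >= mx - 1e-12)
  if (length(idx) == 1) return(idx)
  # center of the longest contiguous run of maxima
  runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
  run <- runs[[which.max(lengths(runs))]]
  run[ceiling(length(run) / 2)]
}

#' Activation time map
#'
#' Activation = time of the maximum temporal derivative of each trace
#' within the analysis window (the optical-mapping dV/dt-max convention),
#' refined by parabolic sub-sample interpolation; alternatively the 50%
#' amplitude crossing. Flat traces yield missing values.
#'
#' @param signals N x T matrix of traces (rows = faces or pixels),
#'   normalized to `[0, 1]`; NA rows allowed.
#' @param sampling_rate Hz.
#' @param window `(start, end)` of the analysis window in ms (default
#'   the whole trace).
#' @param method `"dvdt_max"` (default) or `"midpoint"` (50% crossing).
#' @param mesh optional mesh reference carried in the result.
#' @return A [scalar_surface_map()] of kind `"activation"`, ms.
#' @export
activation_times <- function(signals, sampling_rate, window = NULL,
                             method = c("dvdt_max", "midpoint"),
                             mesh = NULL) {
  method <- match.arg(method)
  signals <- as.matrix(signals)
  Tn <- ncol(signals)
  dt_ms <- 1000 / sampling_rate
  tms <- (seq_len(Tn) - 1) * dt_ms
  if (is.null(window)) window <- c(tms[1], tms[Tn])
  sel <- which(tms >= window[1] & tms <= window[2])
  out <- rep(NA_real_, nrow(signals))
  for (i in seq_len(nrow(signals))) {
    y <- signals[i, sel]
    if (anyNA(y) || max(y) - min(y) <= 1e-12) next
    if (method == "dvdt_max") {
      dy <- diff(y)
      k <- .argmax_center(dy)
      kk <- .parabolic_peak(dy, k)
      # derivative sample k spans samples k..k+1: centered at k + 1/2
      out[i] <- tms[sel[1]] + (kk - 1 + 0.5) * dt_ms
    } else {
      half <- (max(y) + min(y)) / 2
      k <- which(y[-1] >= half & y[-length(y)] < half)[1]
      if (is.na(k)) next
      frac <- (half - y[k]) / (y[k + 1] - y[k])
      out[i] <- tms[sel[1]] + (k - 1 + frac) * dt_ms
    }
  }
  scalar_surface_map(out, "activation", mesh, "ms")
}

#' Action potential duration (APD) map
#'
#' APD at `level` (default 0.8, i.e. APD80) = time after the AP peak at
#' which the trace first falls below
#' `peak - level * (peak - baseline)`, minus the activation time, with
#' linear interpolation between samples. The diastolic baseline is the
#' trace minimum within the window. Traces that never recover within the
#' window are missing. APD is invariant to affine rescaling of the trace.
#'
#' @param signals N x T matrix of traces.
#' @param activation a [scalar_surface_map()] from [activation_times()].
#' @param sampling_rate Hz.
#' @param level repolarization fraction (default 0.8).
#' @param window optional `(start, end)` ms analysis window.
#' @return A [scalar_surface_map()] of kind `"apd"`, ms.
#' @export
apd_map <- function(signals, activation, sampling_rate, level = 0.8,
                    window = NULL) {
  signals <- as.matrix(signals)
  Tn <- ncol(signals)
  dt_ms <- 1000 / sampling_rate
  tms <- (seq_len(Tn) - 1) * dt_ms
  if (is.null(window)) window <- c(tms[1], tms[Tn])
  sel <- which(tms >= window[1] & tms <= window[2])
  out <- rep(NA_real_, nrow(signals))
  for (i in seq_len(nrow(signals))) {
    act <- activation$values[i]
    y <- signals[i, sel]
    if (is.na(act) || anyNA(y) || max(y) - min(y) <= 1e-12) next
    base <- min(y)
    pk <- .argmax_center(y)
    peak <- y[pk]
    thr <- peak - level * (peak - base)
    below <- which(y[pk:length(y)] < thr)
    if (length(below) == 0) next
    k <- pk + below[1] - 1       # first sample below threshold
    if (k == pk) next            # peak itself below: degenerate
    frac <- (y[k - 1] - thr) / (y[k - 1] - y[k])
    t_cross <- tms[sel[1]] + (k - 2 + frac) * dt_ms
    apd <- t_cross - act
    if (apd > 0) out[i] <- apd
  }
  scalar_surface_map(out, "apd", activation$mesh, "ms")
}

# Welch power spectral density: Hann-windowed segments, 50% overlap,
# averaged periodograms
.welch_psd <- function(x, fs, nperseg = min(length(x), 1024)) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1, floor(nperseg / 2))
  starts <- seq(1, n - nperseg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  U <- sum(w^2)
  nfreq <- floor(nperseg / 2) + 1
  p <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg))^2 / (U * fs)
    p <- p + sp[seq_len(nfreq)]
  }
  list(freq = (seq_len(nfreq) - 1) * fs / nperseg,
       power = p / length(starts))
}

#' Dominant frequency map
#'
#' Per-trace Welch periodogram (Hann windows, 50% overlap) peak within
#' the search band. Used to characterize fibrillation from projected
#' signals. All-zero or missing traces yield missing values.
#'
#' @param signals N x T matrix of traces.
#' @param sampling_rate Hz.
#' @param band `(low, high)` search band in Hz (default `c(0.5, 50)`).
#' @param nperseg Welch segment length in samples (default
#'   `min(T, 1024)`).
#' @param mesh optional mesh reference.
#' @return A [scalar_surface_map()] of kind `"df"`, Hz.
#' @export
dominant_frequency_map <- function(signals, sampling_rate,
                                   band = c(0.5, 50), nperseg = NULL,
                                   mesh = NULL) {
  signals <- as.matrix(signals)
  if (is.null(nperseg)) nperseg <- min(ncol(signals), 1024)
  out <- rep(NA_real_, nrow(signals))
  for (i in seq_len(nrow(signals))) {
    y <- signals[i, ]
    if (anyNA(y) || all(y == 0) || stats::sd(y) == 0) next
    psd <- .welch_psd(y, sampling_rate, nperseg)
    inb <- psd$freq >= band[1] & psd$freq <= band[2]
    if (!any(inb)) next
    out[i] <- psd$freq[inb][which.max(psd$power[inb])]
  }
  scalar_surface_map(out, "df", mesh, "Hz")
}

# analytic signal via FFT (Hilbert transform)
.analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of every trace
#'
#' Phase = argument of the analytic signal (Hilbert transform) of each
#' mean-subtracted trace, wrapped to `(-pi, pi]`. Constant traces have
#' undefined phase and are returned as missing.
#'
#' @param signals N x T matrix of traces (detrended/normalized).
#' @param sampling_rate Hz.
#' @return An object of class `phase_field`: `phase` (N x T matrix) and
#'   `sampling_rate`.
#' @export
compute_phase <- function(signals, sampling_rate) {
  signals <- as.matrix(signals)
  if (ncol(signals) < 4) stop("trace too short for phase analysis (< 4 samples)")
  ph <- matrix(NA_real_, nrow(signals), ncol(signals))
  for (i in seq_len(nrow(signals))) {
    y <- signals[i, ]
    if (anyNA(y) || stats::sd(y) == 0) next
    a <- .analytic_signal(y - mean(y))
    p <- Arg(a)
    p[p <= -pi] <- p[p <= -pi] + 2 * pi
    ph[i, ] <- p
  }
  structure(list(phase = ph, sampling_rate = sampling_rate),
            class = "phase_field")
}

.wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- y[y <= -pi] + 2 * pi
  y
}

#' Detect phase singularities in a wrapped-phase image
#'
#' For every 2 x 2 pixel loop the four wrapped phase differences are
#' summed; a sum of +-2 pi marks a phase singularity (spiral-wave rotor
#' core) of topological charge +-1 at the loop center. Smooth phase
#' fields give zero everywhere.
#'
#' @param phase_frame H x W matrix of phases in `(-pi, pi]`.
#' @param tol numeric tolerance on `|sum| - 2 pi` (default 1e-6).
#' @return data.frame with columns `u`, `v` (loop center, 0-based pixel
#'   coordinates), `chirality` (+1 / -1).
#' @export
detect_phase_singularities <- function(phase_frame, tol = 1e-6) {
  p <- as.matrix(phase_frame)
  H <- nrow(p); W <- ncol(p)
  p00 <- p[-H, -W]; p01 <- p[-H, -1]; p11 <- p[-1, -1]; p10 <- p[-1, -W]
  # counterclockwise loop in (u, v): right, down, left, up
  s <- .wrap_phase(p01 - p00) + .wrap_phase(p11 - p01) +
    .wrap_phase(p10 - p11) + .wrap_phase(p00 - p10)
  hit <- which(abs(abs(s) - 2 * pi) < tol, arr.ind = TRUE)
  data.frame(u = hit[, 2] - 1 + 0.5, v = hit[, 1] - 1 + 0.5,
             chirality = sign(s[hit]))
}

#' Phase singularities across all frames of a phase field raster movie
#'
#' @param phase_movie H x W x T array of wrapped phase.
#' @param tol tolerance passed to [detect_phase_singularities()].
#' @return data.frame with columns `u`, `v`, `chirality`, `frame`.
#' @export
track_phase_singularities <- function(phase_movie, tol = 1e-6) {
  out <- lapply(seq_len(dim(phase_movie)[3]), function(t) {
    ps <- detect_phase_singularities(phase_movie[, , t], tol)
    if (nrow(ps) > 0) ps$frame <- t
    ps
  })
  do.call(rbind, out[vapply(out, nrow, 1L) > 0])
}
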