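toy_movie <- function(frames, fs = 1000, mask = NULL)
  optical_movie(frames, fs, mask = mask)

test_that("normalization maps every foreground trace onto [0, 1]", {
  fr <- array(0, c(1, 1, 3))
  fr[1, 1, ] <- c(2, 4, 6)
  expect_equal(drop(normalize_traces(toy_movie(fr))$frames), c(0, 0.5, 1))

  fr[1, 1, ] <- c(0, 0.25, 1)
  expect_equal(drop(normalize_traces(toy_movie(fr))$frames), c(0, 0.25, 1))

  set.seed(1)
  fr <- array(stats::rnorm(5 * 4 * 30), c(5, 4, 30))
  nm <- normalize_traces(toy_movie(fr))
  M <- matrix(nm$frames, 20)
  expect_equal(unname(apply(M, 1, min)), rep(0, 20))
  expect_equal(unname(apply(M, 1, max)), rep(1, 20))
})

test_that("constant foreground traces are flagged and moved to background", {
  fr <- array(stats::rnorm(2 * 2 * 10), c(2, 2, 10))
  fr[1, 1, ] <- 3
  expect_warning(out <- normalize_traces(toy_movie(fr)), "constant")
  expect_equal(out$mask[1, 1], 0)
  expect_true(all(out$frames[1, 1, ] == 0))
})

test_that("spatial binning averages only over foreground", {
  fr <- array(2.5, c(5, 5, 3))
  expect_equal(spatial_bin(toy_movie(fr), 1), toy_movie(fr))
  expect_equal(spatial_bin(toy_movie(fr), 3)$frames, fr)

  hot <- array(0, c(5, 5, 2))
  hot[3, 3, ] <- 9
  out <- spatial_bin(toy_movie(hot), 3)
  expect_equal(out$frames[2:4, 2:4, 1], matrix(1, 3, 3))
  expect_equal(out$frames[1, 1, 1], 0)

  # background never contaminates: foreground average unchanged by a
  # huge background value
  msk <- matrix(1, 5, 5); msk[1, 1] <- 0
  fr2 <- array(1, c(5, 5, 2)); fr2[1, 1, ] <- 1e6
  out2 <- spatial_bin(toy_movie(fr2, mask = msk), 3)
  expect_equal(out2$frames[2, 2, 1], 1)
})

test_that("the temporal filter keeps DC and the passband, kills 150 Hz", {
  taps <- design_temporal_filter(100, 100, 1000)
  expect_equal(length(taps), 101)
  expect_lt(abs(sum(taps) - 1), 1e-6)   # DC gain
  hf <- function(fq) abs(sum(taps * exp(-2i * pi * fq / 1000 *
                                          (0:100))))
  expect_lt(20 * log10(hf(150)), -20)   # >= 20 dB down at 150 Hz
  expect_lt(abs(hf(10) - 1), 0.02)      # 10 Hz preserved within 2%

  t_ <- (0:999) / 1000
  const <- array(0.7, c(1, 1, 1000))
  expect_equal(filter_temporal(toy_movie(const))$frames, const,
               tolerance = 1e-9)

  sine10 <- array(sin(2 * pi * 10 * t_), c(1, 1, 1000))
  out <- drop(filter_temporal(toy_movie(sine10))$frames)
  mid <- 200:800   # away from the padded edges
  ref <- sin(2 * pi * 10 * t_)[mid]
  expect_lt(max(abs(out[mid] - ref)), 0.02)  # amplitude and phase intact

  sine150 <- array(sin(2 * pi * 150 * t_), c(1, 1, 1000))
  out150 <- drop(filter_temporal(toy_movie(sine150))$frames)
  expect_lt(max(abs(out150[mid])), 0.1)

  expect_error(filter_temporal(toy_movie(const, fs = 150)),
               "sampling rate too low")
})

test_that("first-order drift removal strips lines, keeps signal", {
  tt <- 0:199
  line <- array(0.003 * tt + 2, c(1, 1, 200))
  out <- drop(remove_drift(toy_movie(line))$frames)
  expect_lt(max(out) - min(out), 1e-9)
  expect_equal(mean(out), mean(line), tolerance = 1e-9)

  # an even-symmetric oscillation (orthogonal to the centered line)
  sine <- cos(2 * pi * 2 * (tt - 99.5) / 200)
  pure <- array(sine, c(1, 1, 200))
  expect_equal(drop(remove_drift(toy_movie(pure))$frames), sine,
               tolerance = 1e-9)

  both <- array(sine + 0.01 * tt - 3, c(1, 1, 200))
  rec <- drop(remove_drift(toy_movie(both))$frames)
  expect_lt(sqrt(mean((rec - mean(rec) - (sine - mean(sine)))^2)), 1e-6)
})

test_that("polygon masking matches a ray-casting point-in-polygon oracle", {
  set.seed(2)
  fr <- array(stats::rnorm(20 * 20 * 3), c(20, 20, 3))
  mv <- toy_movie(fr)

  whole <- mask_region(mv, rbind(c(-1, -1), c(25, -1), c(25, 25), c(-1, 25)))
  expect_equal(sum(whole$mask), 0)

  degen <- mask_region(mv, rbind(c(3, 3), c(3, 3), c(3, 3)))
  expect_equal(degen, mv)

  expect_error(mask_region(mv, rbind(c(0, 0), c(10, 10), c(10, 0),
                                     c(0, 10))), "invalid polygon")

  # half-plane-ish polygon: count removed pixels vs crossing-number oracle
  poly <- rbind(c(-0.5, -0.5), c(9.3, -0.5), c(12.8, 20.5), c(-0.5, 20.5))
  out <- mask_region(mv, poly)
  oracle_inside <- function(u, v) {
    n <- nrow(poly); cross <- 0
    for (i in 1:n) {
      a <- poly[i, ]; b <- poly[(i %% n) + 1, ]
      if ((a[2] > v) != (b[2] > v)) {
        xi <- a[1] + (v - a[2]) / (b[2] - a[2]) * (b[1] - a[1])
        if (u < xi) cross <- cross + 1
      }
    }
    cross %% 2 == 1
  }
  cnt <- 0
  for (u in 0:19) for (v in 0:19) if (oracle_inside(u, v)) cnt <- cnt + 1
  expect_equal(sum(out$mask == 0), cnt)
  # idempotent
  expect_equal(mask_region(out, poly), out)
})

test_that("weight masks hit the 0.5 and 1 endpoints", {
  single <- matrix(0, 5, 5); single[3, 3] <- 1
  expect_equal(build_weight_mask(single)$weights[3, 3], 1)

  disk <- matrix(0, 101, 101)
  u <- matrix(rep(0:100, each = 101), 101)
  v <- matrix(rep(0:100, times = 101), 101)
  disk[(u - 50)^2 + (v - 50)^2 <= 40^2] <- 1
  w <- build_weight_mask(disk)$weights
  expect_equal(w[51, 51], 1)             # center
  # outermost foreground pixels (adjacent to background) get exactly 0.5
  edge <- disk == 1 &
    (rbind(disk[-1, ], 0) == 0 | rbind(0, disk[-101, ]) == 0 |
       cbind(disk[, -1], 0) == 0 | cbind(0, disk[, -101]) == 0)
  expect_true(all(w[edge] == 0.5))
  expect_true(all(w[disk == 1] >= 0.5 & w[disk == 1] <= 1))
  expect_true(all(w[disk == 0] == 0))

  # arbitrary mask against a brute-force distance-transform oracle
  set.seed(8)
  m <- matrix(0, 15, 15)
  m[4:12, 3:13] <- 1
  m[9, 9] <- 0
  wm <- build_weight_mask(m)$weights
  fg <- which(m == 1, arr.ind = TRUE)
  bg <- which(m == 0, arr.ind = TRUE)
  d <- apply(fg, 1, function(p)
    min(sqrt((bg[, 1] - p[1])^2 + (bg[, 2] - p[2])^2)))
  expected <- 0.5 + 0.5 * (d - min(d)) / (max(d) - min(d))
  expect_equal(wm[fg], expected, tolerance = 1e-12)

  expect_error(build_weight_mask(matrix(0, 4, 4)), "empty mask")
})

test_that("the conditioning pipeline preserves shape and mask", {
  set.seed(3)
  fr <- array(stats::runif(10 * 10 * 400), c(10, 10, 400))
  msk <- matrix(1, 10, 10); msk[1, ] <- 0
  mv <- toy_movie(fr, mask = msk)
  out <- condition_movie(mv)
  expect_equal(dim(out$frames), dim(fr))
  expect_equal(out$mask, msk)
  expect_true(all(out$frames[1, , ] == 0))
})
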