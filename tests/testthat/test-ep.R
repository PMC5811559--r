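test_that("activation is the maximum-derivative time", {
  fs <- 1000
  # step upstroke at sample 51 (50 ms)
  step <- c(rep(0, 50), rep(1, 50))
  act <- activation_times(rbind(step), fs)
  expect_lt(abs(act$values[1] - 49.5), 0.5)   # within half a sample

  # linear ramp: constant derivative, tie broken to the ramp center
  ramp <- c(rep(0, 20), seq(0, 1, length.out = 21), rep(1, 20))
  act2 <- activation_times(rbind(ramp), fs)
  expect_lt(abs(act2$values[1] - 30), 1)      # midpoint of the ramp, ms

  # flat trace -> missing
  expect_true(is.na(activation_times(rbind(rep(0.3, 60)), fs)$values[1]))

  # translation equivariance: shifting traces shifts times exactly
  tpl <- ap_template(upstroke_time = 30)
  t_ms <- seq(0, 200, by = 1)
  tr <- ap_trace(tpl, t_ms)
  tr_shift <- ap_trace(tpl, t_ms - 40)
  a1 <- activation_times(rbind(tr), fs)$values[1]
  a2 <- activation_times(rbind(tr_shift), fs)$values[1]
  expect_equal(a2 - a1, 40, tolerance = 1e-9)
})

test_that("activation gradient of a plane wave recovers conduction speed", {
  v <- 0.05   # units per ms
  xs <- seq(0, 2, length.out = 40)
  tpl <- ap_template(upstroke_time = 0, upstroke_duration = 2)
  t_ms <- seq(0, 150, by = 1)
  sig <- t(vapply(xs, function(x) ap_trace(tpl, t_ms - x / v), t_ms))
  act <- activation_times(sig, 1000)
  slope <- stats::coef(stats::lm(act$values ~ xs))[2]
  expect_lt(abs(slope - 1 / v) / (1 / v), 0.05)
})

test_that("APD matches closed-form crossings of the template family", {
  fs <- 1000
  # instantaneous upstroke at 20 ms, peak 1, linear fall over 100 ms
  tpl0 <- ap_template(upstroke_time = 20, upstroke_duration = 0,
                      plateau_duration = 0, repolarization_duration = 100)
  t_ms <- seq(0, 180, by = 1)
  tr <- rbind(ap_trace(tpl0, t_ms))
  act <- activation_times(tr, fs)
  apd80 <- apd_map(tr, act, fs, level = 0.8)
  expect_lte(abs(apd80$values[1] - 80), 0.5)   # half a sample
  apd100 <- apd_map(tr, act, fs, level = 0.999999)
  expect_lte(abs(apd100$values[1] - 100), 0.5)

  set.seed(21)
  for (i in 1:10) {
    tpl <- ap_template(upstroke_time = stats::runif(1, 5, 30),
                       upstroke_duration = stats::runif(1, 1, 4),
                       plateau_duration = stats::runif(1, 10, 60),
                       repolarization_duration = stats::runif(1, 40, 120))
    lvl <- stats::runif(1, 0.3, 0.9)
    t_ms2 <- seq(0, 400, by = 1)
    tr2 <- rbind(ap_trace(tpl, t_ms2))
    a <- activation_times(tr2, fs)
    apd <- apd_map(tr2, a, fs, level = lvl)
    expect_lt(abs(apd$values[1] - analytic_apd(tpl, lvl)), 0.5)
  }

  # affine invariance: a * s + b leaves APD unchanged
  tr3 <- rbind(3.2 * ap_trace(tpl0, t_ms) + 0.4)
  act3 <- activation_times(rbind(ap_trace(tpl0, t_ms)), fs)
  apd3 <- apd_map(tr3, act3, fs, level = 0.8)
  expect_equal(apd3$values[1], apd80$values[1], tolerance = 1e-9)

  # no recovery within the window -> missing
  tpl_long <- ap_template(upstroke_time = 10, plateau_duration = 500)
  trl <- rbind(ap_trace(tpl_long, seq(0, 200, by = 1)))
  al <- activation_times(trl, fs)
  expect_true(is.na(apd_map(trl, al, fs)$values[1]))
})

test_that("dominant frequency finds the spectral peak in band", {
  fs <- 1000
  t_ <- seq(0, 4, by = 1 / fs)
  s7 <- rbind(sin(2 * pi * 7 * t_))
  df <- dominant_frequency_map(s7, fs)
  expect_lt(abs(df$values[1] - 7), fs / 1024)   # within one bin

  mix <- rbind(sin(2 * pi * 5 * t_) + 0.3 * sin(2 * pi * 12 * t_))
  expect_lt(abs(dominant_frequency_map(mix, fs)$values[1] - 5), fs / 1024)

  expect_true(is.na(dominant_frequency_map(rbind(rep(0, 4000)),
                                           fs)$values[1]))

  set.seed(4)
  noise <- rbind(stats::rnorm(4000))
  v <- dominant_frequency_map(noise, fs, band = c(0.5, 50))$values[1]
  expect_true(v >= 0.5 && v <= 50)
})

test_that("Welch periodogram peak agrees with spec.pgram on a test tone", {
  fs <- 500
  t_ <- seq(0, 6, by = 1 / fs)
  x <- sin(2 * pi * 11 * t_) + 0.2 * stats::rnorm(length(t_))
  ours <- dominant_frequency_map(rbind(x), fs, band = c(1, 50))$values[1]
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), plot = FALSE,
                          taper = 0)
  inb <- sp$freq >= 1 & sp$freq <= 50
  ref <- sp$freq[inb][which.max(sp$spec[inb])]
  expect_lt(abs(ours - ref), 1)
})

test_that("Hilbert phase behaves like the analytic signal", {
  fs <- 500
  t_ <- seq(0, 2 - 1 / fs, by = 1 / fs)
  f0 <- 6
  ph <- compute_phase(rbind(sin(2 * pi * f0 * t_)), fs)
  p <- ph$phase[1, ]
  expect_true(all(p > -pi & p <= pi))
  dp <- diff(p)
  dp <- (dp + pi) %% (2 * pi) - pi
  mid <- 100:900
  expect_lt(max(abs(dp[mid] - 2 * pi * f0 / fs)), 0.05)

  # constant trace -> missing phase
  ph0 <- compute_phase(rbind(rep(1, 100)), fs)
  expect_true(all(is.na(ph0$phase[1, ])))

  # cos leads sin by pi/2
  both <- compute_phase(rbind(cos(2 * pi * f0 * t_),
                              sin(2 * pi * f0 * t_)), fs)
  dphi <- both$phase[1, mid] - both$phase[2, mid]
  dphi <- (dphi + pi) %% (2 * pi) - pi
  expect_lt(max(abs(dphi - pi / 2)), 0.05)

  expect_error(compute_phase(rbind(1:3), fs), "too short")
})

test_that("phase singularities carry unit topological charge", {
  spiral <- synth_spiral_phase_field(c(41, 41), c(20.5, 20.5), chirality = 1)
  ps <- detect_phase_singularities(spiral)
  expect_equal(nrow(ps), 1)
  expect_equal(ps$chirality, 1)
  expect_lt(max(abs(c(ps$u, ps$v) - 20.5)), 1)

  neg <- synth_spiral_phase_field(c(41, 41), c(20.5, 20.5), chirality = -1)
  psn <- detect_phase_singularities(neg)
  expect_equal(psn$chirality, -1)

  # mirrored pair: net charge 0
  pair <- synth_spiral_phase_field(c(41, 81), c(20.5, 20.5), 1) +
    synth_spiral_phase_field(c(41, 81), c(60.5, 20.5), -1)
  pair <- (pair + pi) %% (2 * pi) - pi
  ps2 <- detect_phase_singularities(pair)
  expect_equal(sum(ps2$chirality), 0)
  expect_equal(nrow(ps2), 2)

  # smooth singularity-free field: all loop sums vanish (brute-force
  # winding oracle over every 2x2 loop)
  u <- matrix(rep(0:30, each = 31), 31)
  v <- matrix(rep(0:30, times = 31), 31)
  smooth <- (0.15 * u + 0.08 * v + pi) %% (2 * pi) - pi
  expect_equal(nrow(detect_phase_singularities(smooth)), 0)
  wrap <- function(x) (x + pi) %% (2 * pi) - pi
  for (i in sample(1:30, 5)) for (j in sample(1:30, 5)) {
    s <- wrap(smooth[i, j + 1] - smooth[i, j]) +
      wrap(smooth[i + 1, j + 1] - smooth[i, j + 1]) +
      wrap(smooth[i + 1, j] - smooth[i + 1, j + 1]) +
      wrap(smooth[i, j] - smooth[i + 1, j])
    expect_lt(abs(s), 1e-9)
  }
})

test_that("boundary winding equals the summed singularity charges", {
  set.seed(6)
  for (chir in list(c(1, 1), c(1, -1))) {
    f <- synth_spiral_phase_field(c(51, 51), c(15.5, 25.5), chir[1]) +
      synth_spiral_phase_field(c(51, 51), c(35.5, 25.5), chir[2])
    f <- (f + pi) %% (2 * pi) - pi
    ps <- detect_phase_singularities(f)
    wrap <- function(x) (x + pi) %% (2 * pi) - pi
    ring <- c(f[1, 1:51], f[2:51, 51], f[51, 50:1], f[50:2, 1])
    winding <- sum(wrap(diff(c(ring, ring[1])))) / (2 * pi)
    expect_equal(sum(ps$chirality), round(winding))
  }
})
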