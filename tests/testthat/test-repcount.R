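# Peak-detection repetition counter: dominant axis, smoothing, thresholds,
# alternating extrema, and counting.

sine_rec <- function(cycles = 6, fs = 64, channel = "gyro_y", amp = 100) {
  n <- cycles * 4 * fs
  tt <- (0:(n - 1)) / fs
  m <- matrix(0, n, 6)
  colnames(m) <- c("acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z")
  m[, channel] <- amp * sin(2 * pi * tt / 4)
  imu_recording("S1", "TT", "constrained", fs, tt, m[, 1:3], m[, 4:6])
}

test_that("dominant axis follows the configured channel and tie-breaks", {
  sim <- simulate_exercise(test_profiles()$BC, 6, fs = 64, seed = 1)
  d <- dominant_axis(sim$recording)
  expect_equal(d$sensor, "accelerometer")
  expect_equal(d$axis, "X")
  # pure sinusoid on gyro-Y only
  d2 <- dominant_axis(sine_rec())
  expect_equal(d2$sensor, "gyroscope")
  expect_equal(d2$axis, "Y")
  # exact two-channel tie: first in channel order wins
  n <- 256
  tt <- (0:(n - 1)) / 64
  s <- sin(2 * pi * tt)
  acc <- cbind(s, s, 0 * s)
  d3 <- dominant_axis(imu_recording("S1", "BC", "constrained", 64, tt, acc,
                                    matrix(0, n, 3)))
  expect_equal(d3$channel, "acc_x")
  # constant recording is degenerate
  d4 <- dominant_axis(imu_recording("S1", "BC", "constrained", 64, tt,
                                    matrix(1, n, 3), matrix(0, n, 3)))
  expect_true(d4$degenerate)
})

test_that("Savitzky-Golay smoothing is exact on low-order polynomials", {
  cfg <- peak_config(fs = 64)  # window 127, order 4
  tt <- seq(-1, 1, length.out = 600)
  poly <- 2 + tt - 3 * tt^2 + 0.5 * tt^4
  sm <- smooth_signal(poly, cfg)
  interior <- 64:(600 - 64)
  expect_equal(sm[interior], poly[interior], tolerance = 1e-8)
  expect_equal(smooth_signal(rep(5, 600), cfg), rep(5, 600), tolerance = 1e-10)
  # noise suppression brings the signal closer to the clean sine
  set.seed(2)
  clean <- sin(2 * pi * (0:999) / 256)
  noisy <- clean + rnorm(1000, sd = 0.3)
  sm2 <- smooth_signal(noisy, cfg)
  expect_lt(sqrt(mean((sm2 - clean)^2)), sqrt(mean((noisy - clean)^2)))
  # too-short signal shrinks the window with a warning
  expect_warning(out <- smooth_signal(sin(1:50), peak_config(fs = 64)),
                 "shrunk")
  expect_length(out, 50)
})

test_that("thresholds are quantile-based, symmetric and shift-equivariant", {
  x <- sin(2 * pi * (0:9999) / 500)
  th <- compute_thresholds(x, peak_config(fs = 64))
  # closed form: median 0, half quantile span = sin(0.45 pi) approximately
  a <- sin(0.45 * pi)
  expect_equal(th$upper, 0.3 * a, tolerance = 0.02)
  expect_equal(th$lower, -0.3 * a, tolerance = 0.02)
  th2 <- compute_thresholds(x + 7, peak_config(fs = 64))
  expect_equal(th2$upper - th$upper, 7, tolerance = 1e-9)
  expect_equal(th2$lower - th$lower, 7, tolerance = 1e-9)
  expect_true(compute_thresholds(rep(1, 100))$degenerate)
})

test_that("peak detection alternates and skips sub-threshold cycles", {
  fs <- 64
  tt <- (0:(6 * 4 * fs - 1)) / fs
  x <- sin(2 * pi * tt / 4)
  th <- list(upper = 0.3, lower = -0.3, degenerate = FALSE)
  det <- detect_peaks(x, th)
  expect_length(det$peaks, 6)
  expect_length(det$valleys, 6)
  expect_identical(det$extrema$type, rep(c("max", "min"), 6))
  expect_true(all(diff(det$extrema$index) > 0))
  # one attenuated cycle skipped, matching brute-force extrema of the rest
  x2 <- x
  cyc3 <- tt >= 8 & tt < 12
  x2[cyc3] <- 0.2 * x2[cyc3]
  det2 <- detect_peaks(x2, th)
  expect_length(det2$peaks, 5)
  expect_length(det2$valleys, 5)
  # monotone ramp yields nothing
  expect_length(detect_peaks(seq(0, 2, length.out = 500), th)$peaks, 0)
})

test_that("noiseless trials are counted exactly and flat recordings give 0", {
  trials <- noiseless_trials()
  for (lab in names(trials)) {
    res <- count_reps_peaks(trials[[lab]]$recording)
    expect_equal(res$rep_count, trials[[lab]]$truth$n_reps, info = lab)
    expect_equal(res$dominant$sensor, test_profiles()[[lab]]$dominant_sensor,
                 info = lab)
  }
  n <- 600
  flat <- imu_recording("S1", "BC", "constrained", 64, (0:(n - 1)) / 64,
                        matrix(0.5, n, 3), matrix(0, n, 3))
  res0 <- count_reps_peaks(flat)
  expect_equal(res0$rep_count, 0L)
  expect_true(res0$degenerate)
})

test_that("the counter is invariant to amplitude scale and offset", {
  sim <- simulate_exercise(test_profiles()$LLR, 7, fs = 64, seed = 9)
  rec <- sim$recording
  base <- count_reps_peaks(rec)$rep_count
  for (c_scale in c(0.5, 3)) {
    rec2 <- rec
    rec2$acc <- rec$acc * c_scale
    rec2$gyro <- rec$gyro * c_scale
    expect_equal(count_reps_peaks(rec2)$rep_count, base, info = c_scale)
  }
  rec3 <- rec
  rec3$acc <- rec$acc + 0.5
  expect_equal(count_reps_peaks(rec3)$rep_count, base)
})

test_that("default-noise unconstrained trials stay within one repetition", {
  p <- test_profiles()
  errs <- integer(0)
  for (lab in exercise_only_labels()) {
    for (s in 1:10) {
      n <- 6 + (s %% 3)
      sim <- simulate_exercise(p[[lab]], n, fs = 64, mode = "unconstrained",
                               seed = s)
      errs <- c(errs, abs(count_reps_peaks(sim$recording)$rep_count - n))
    }
  }
  expect_gte(mean(errs <= 1), 0.9)
})
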