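# Sliding windows, the 48-feature extractor, entropy/energy estimators, PCA.

test_that("window counts follow floor((N - W)/S) + 1, checked by brute force", {
  p <- test_profiles()
  sim <- simulate_exercise(p$BC, 8, fs = 512, mode = "constrained", seed = 1)
  rec <- sim$recording
  n25 <- 25 * 512
  rec25 <- imu_recording(rec$subject_id, rec$exercise_label, rec$session, 512,
                         rec$t[1:n25], rec$acc[1:n25, ], rec$gyro[1:n25, ])
  expect_length(sliding_windows(rec25, 4, 0.5), 43)

  sim30 <- simulate_exercise(test_profiles()$FR, 10, fs = 64,
                             mode = "constrained", seed = 2)
  rec30 <- sim30$recording  # 30 s at period 3 s? no: 10 reps x 4 s = 40 s
  expect_length(sliding_windows(rec30, 2, 1),
                floor((length(rec30$t) - 2 * 64) / 64) + 1)

  # brute-force enumeration over assorted (N, W, S)
  count_windows <- function(n, w, s) {
    k <- 0
    start <- 1
    while (start + w - 1 <= n) {
      k <- k + 1
      start <- start + s
    }
    k
  }
  for (dur in c(4, 7.5, 12)) {
    fs <- 64
    simx <- simulate_exercise(test_profiles()$TT, ceiling(dur / 4), fs = fs,
                              mode = "constrained", seed = 3)
    recx <- simx$recording
    for (len in c(1, 2, 4)) {
      for (stride in c(0.5, 1, 2)) {
        expected <- count_windows(length(recx$t), len * fs, stride * fs)
        got <- length(suppressWarnings(sliding_windows(recx, len, stride)))
        expect_equal(got, expected, info = paste(dur, len, stride))
      }
    }
  }
  # too short: empty with warning
  short <- imu_recording("S1", "BC", "constrained", 64, (0:100) / 64,
                         matrix(0, 101, 3), matrix(0, 101, 3))
  expect_warning(w0 <- sliding_windows(short, 4, 0.5), "shorter")
  expect_length(w0, 0)
})

test_that("histogram entropy matches closed-form cases", {
  expect_equal(shannon_entropy(rep(3.7, 50), 16), 0)
  expect_equal(shannon_entropy(rep(1:16, each = 4), 16), 4)
  expect_equal(shannon_entropy(seq(0, 255, length.out = 256), 16), 4)
  expect_gte(shannon_entropy(rnorm(100), 16), 0)
})

test_that("spectral energy equals time-domain variance (Parseval)", {
  expect_equal(fft_energy(rep(2, 64)), 0)
  x <- sin(2 * pi * (0:255) / 64)  # 4 integer cycles, unit amplitude
  expect_equal(fft_energy(x), 0.5, tolerance = 1e-12)
  for (s in 1:20) {
    set.seed(s)
    w <- rnorm(128 + s)
    expect_equal(fft_energy(w), mean((w - mean(w))^2), tolerance = 1e-9)
  }
  # offset invariance
  set.seed(1)
  v <- rnorm(64)
  expect_equal(fft_energy(v), fft_energy(v + 100), tolerance = 1e-9)
})

test_that("the feature vector has 48 named entries in the frozen order", {
  m <- random_window(1)
  fv <- extract_features(m)
  expect_length(fv, 48)
  expect_identical(names(fv), feature_names())
  # bit-identical on repeated calls
  expect_identical(fv, extract_features(m))
  # all-zero window: every statistic zero
  z <- extract_features(matrix(0, 64, 6))
  expect_true(all(z == 0))
})

test_that("correlation features hit +/-1 for identical and negated channels", {
  w <- 128
  s <- sin(2 * pi * (0:(w - 1)) / 32)
  m <- cbind(s, s, rnorm(w), rnorm(w, sd = 50), rnorm(w, sd = 50),
             rnorm(w, sd = 50))
  fv <- extract_features(m)
  expect_equal(unname(fv["cor.acc_xy"]), 1)
  m2 <- m
  m2[, 2] <- -s
  expect_equal(unname(extract_features(m2)["cor.acc_xy"]), -1)
  # zero-variance pair defined as 0
  m3 <- m
  m3[, 2] <- 0
  expect_equal(unname(extract_features(m3)["cor.acc_xy"]), 0)
})

test_that("PCA retention follows the accumulated-variance rule", {
  set.seed(4)
  # rank-1 data
  r1 <- outer(rnorm(60), rnorm(48))
  m1 <- fit_pca(r1, 0.99)
  expect_equal(m1$n_retained, 1L)
  # threshold 1 retains the full rank
  lowrank <- matrix(rnorm(100 * 5), 100, 5) %*% matrix(rnorm(5 * 48), 5, 48)
  mfull <- fit_pca(lowrank, 1.0)
  expect_equal(mfull$n_retained, 5L)
  # isotropic cloud: near-equal eigenvalues force retaining almost all
  iso <- matrix(rnorm(5000 * 48), 5000, 48)
  miso <- fit_pca(iso, 0.99)
  expect_gte(miso$n_retained, 44)
  # variance fractions sum to one
  expect_equal(sum(miso$var_fraction), 1, tolerance = 1e-9)
  # retention is monotone in the threshold
  retained <- vapply(c(0.5, 0.9, 0.99, 0.999),
                     function(th) fit_pca(iso, th)$n_retained, integer(1))
  expect_true(all(diff(retained) >= 0))
})

test_that("projection uses training statistics and bounds reconstruction error", {
  set.seed(5)
  x <- matrix(rnorm(300 * 48), 300, 48) %*% diag(c(rep(3, 6), rep(0.2, 42)))
  model <- fit_pca(x, 0.95)
  scores <- apply_pca(model, x)
  expect_equal(ncol(scores), model$n_retained)
  # projecting the training matrix reproduces the fitted scores
  xs <- scale(x, model$center, model$scale)
  expect_equal(scores, xs %*% model$rotation[, 1:model$n_retained],
               tolerance = 1e-12, ignore_attr = TRUE)
  # reconstruction error <= (1 - captured variance) * total variance
  recon <- scores %*% t(model$rotation[, 1:model$n_retained])
  err <- sum((xs - recon)^2)
  total <- sum(xs^2)
  captured <- sum(model$var_fraction[1:model$n_retained])
  expect_lte(err / total, (1 - captured) + 1e-9)
  # column-count mismatch is a shape error
  expect_error(apply_pca(model, x[, 1:10]), "shape error")
})
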