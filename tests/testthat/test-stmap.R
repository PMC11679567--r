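# Preprocessing: color conversion, temporal normalization, noise injection.

test_that("modified-YUV conversion matches the defining matrix", {
  one <- function(rgb) {
    s <- rgb_region_series(array(rep(rgb, each = 2), c(2, 1, 3)), fps = 30)
    rgb_to_modified_yuv(s)$values[1, 1, ]
  }
  expect_equal(one(c(1, 0, 0)), c(0.299, -0.169, 0.5), tolerance = 1e-12)
  expect_equal(one(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(one(c(255, 255, 255)), c(255, 0, 0), tolerance = 1e-12)
})

test_that("color conversion is exactly linear and shape-preserving", {
  s1 <- make_series(seed = 1)
  s2 <- make_series(seed = 2)
  a <- 0.7; b <- -1.3
  mix <- rgb_region_series(a * s1$values + b * s2$values, fps = 30)
  lhs <- rgb_to_modified_yuv(mix)$values
  rhs <- a * rgb_to_modified_yuv(s1)$values + b * rgb_to_modified_yuv(s2)$values
  expect_lt(max(abs(lhs - rhs)), 1e-12)
  expect_identical(dim(lhs), dim(s1$values))
})

test_that("non-finite input is rejected with a validation error", {
  v <- array(1, c(4, 1, 3)); v[2, 1, 1] <- NA
  expect_error(rgb_region_series(v, fps = 30), "non-finite")
  v[2, 1, 1] <- Inf
  expect_error(rgb_region_series(v, fps = 30), "non-finite")
})

test_that("temporal normalization standardizes every trace (population sd)", {
  expect_equal(pulseband:::zscore_trace(c(1, 2, 3)),
               c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  s <- make_series(nT = 100, nI = 3, seed = 4)
  m <- temporal_normalize(rgb_to_modified_yuv(s))
  expect_true(m$normalized)
  for (i in 1:3) for (c in 1:3) {
    tr <- m$values[, i, c]
    expect_lt(abs(mean(tr)), 1e-6)
    expect_lt(abs(mean((tr - mean(tr))^2) - 1), 1e-6)
  }
})

test_that("constant traces normalize to zeros, not errors", {
  v <- array(5, c(10, 1, 3))
  v[, 1, 2] <- sin(1:10)
  expect_message(m <- temporal_normalize(stmap(v, fps = 30)), "constant")
  expect_equal(m$values[, 1, 1], rep(0, 10))
  expect_gt(pulseband:::pop_sd(m$values[, 1, 2]), 0.9)
})

test_that("temporal normalization is idempotent on non-degenerate traces", {
  s <- make_series(nT = 120, seed = 9)
  m1 <- temporal_normalize(rgb_to_modified_yuv(s))
  m2 <- temporal_normalize(stmap(m1$values, fps = 30))
  expect_lt(max(abs(m1$values - m2$values)), 1e-6)
})

test_that("sliding-window normalization keeps the global contract", {
  s <- make_series(nT = 200, seed = 5)
  m <- temporal_normalize(rgb_to_modified_yuv(s),
                          preprocess_config(tdn_window = 30))
  tr <- m$values[, 1, 1]
  expect_lt(abs(mean(tr)), 1e-6)
  expect_lt(abs(mean((tr - mean(tr))^2) - 1), 1e-6)
})

test_that("white-noise augmentation hits the requested SNR and is seeded", {
  s <- make_series(nT = 450, nI = 1, seed = 6)
  m <- temporal_normalize(rgb_to_modified_yuv(s))
  # Inf sentinel: no-op
  m_inf <- inject_white_noise(m, preprocess_config(noise_snr_db = Inf))
  expect_identical(m_inf$values, m$values)
  # 0 dB on unit-variance traces: added noise variance ~ 1 (Monte-Carlo)
  vars <- replicate(50, {
    cfg <- preprocess_config(noise_snr_db = 0,
                             rng_seed = sample.int(1e6, 1))
    mean((inject_white_noise(m, cfg)$values[, 1, 1] - m$values[, 1, 1])^2)
  })
  expect_lt(abs(mean(vars) - 1), 0.1)
  # determinism under a fixed seed
  cfg <- preprocess_config(noise_snr_db = 10, rng_seed = 33)
  expect_identical(inject_white_noise(m, cfg)$values,
                   inject_white_noise(m, cfg)$values)
})

test_that("frame-array region extraction averages masks and carries dropouts forward", {
  nT <- 6; H <- 4; W <- 4
  frames <- array(0, c(nT, H, W, 3))
  for (t in seq_len(nT)) frames[t, , , ] <- t  # uniform color = t
  mask <- matrix(FALSE, H, W); mask[1:2, 1:2] <- TRUE
  masks <- rep(list(list(mask, !mask)), nT)
  masks[4] <- list(NULL)  # detection dropout at frame 4
  expect_message(s <- video_to_region_series(frames, masks, fps = 30),
                 "dropout")
  expect_equal(dim(s$values), c(nT, 2L, 3L))
  expect_equal(s$values[2, 1, 1], 2)     # uniform color recovered
  expect_equal(s$values[4, , ], s$values[3, , ])  # carried forward
  expect_error(video_to_region_series(frames, rep(list(NULL), nT), fps = 30),
               "no frame")
})

test_that("CSV and container round-trips preserve the data", {
  s <- make_series(nT = 20, nI = 2, seed = 12)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".rds")
  write_stmap_csv(s, f1)
  back <- read_stmap_csv(f1, fps = 30)
  expect_equal(back$values, s$values, tolerance = 1e-12)
  write_container(s, f2)
  expect_identical(read_container(f2)$values, s$values)  # bit-exact
})
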