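# Synthetic rPPG generator: determinism, ground-truth consistency,
# HR-distribution control, disturbance calibration.

test_that("waveform generator honors the requested heart rate", {
  for (hr in c(50, 72, 120, 150)) {
    w <- gen_bvp_waveform(hr, duration_s = 15, fps = 30, lf_depth = 0,
                          hf_depth = 0, seed = 1)
    expect_lt(abs(60 / mean(w$ibi$intervals) - hr), 0.5)
    # no modulation: all beat intervals equal up to a frame
    expect_lt(max(w$ibi$intervals) - min(w$ibi$intervals), 1 / 30)
  }
})

test_that("generator ground-truth IBIs carry the requested modulation", {
  w <- gen_bvp_waveform(70, duration_s = 60, fps = 30, lf_depth = 0.05,
                        hf_depth = 0, seed = 2)
  h <- hrv_lf_hf(w$ibi)
  expect_gte(h$lf_nu, 0.9)
})

test_that("clean maps are affine images of the pulse waveform", {
  cfg <- synth_config(drift_amp = 0, artifact_rate = 0, snr_db = Inf,
                      seed = 3)
  s <- gen_sample(cfg, 1)
  for (i in 1:4) for (c in 1:3)
    expect_equal(abs(cor(s$stmap$values[, i, c], s$gt_bvp)), 1,
                 tolerance = 1e-9)
})

test_that("white-noise level matches the configured SNR", {
  # empirical per-trace SNR at 0 dB within +/- 1 dB, averaged over seeds
  cfg <- synth_config(drift_amp = 0, artifact_rate = 0, snr_db = 0, seed = 4)
  ratio <- replicate(50, {
    i <- sample.int(1e6, 1)
    s <- gen_sample(cfg, i)
    parts <- gen_stmap(s$gt_bvp, cfg, seed = pulseband:::derive_seed(s$seed, 2L),
                       return_parts = TRUE)
    sig <- attr(parts, "parts")$pure[, 1, 2]
    noise <- parts$values[, 1, 2] - sig
    10 * log10(var(sig) / var(noise))
  })
  expect_lt(abs(mean(ratio)), 1)
})

test_that("samples regenerate bit-exactly from (config, index)", {
  cfg <- synth_config(seed = 5)
  s1 <- gen_sample(cfg, 7)
  s2 <- gen_sample(cfg, 7)
  expect_identical(s1$stmap$values, s2$stmap$values)
  expect_identical(s1$gt_bvp, s2$gt_bvp)
  s3 <- gen_sample(cfg, 8)
  expect_gt(max(abs(s3$stmap$values - s1$stmap$values)), 0)
})

test_that("gt_hr is consistent with the ground-truth IBI series", {
  ds <- gen_dataset(synth_config(n_samples = 10, seed = 6))
  for (s in ds$samples)
    expect_lt(abs(s$gt_hr - 60 / mean(s$gt_ibi$intervals)), 0.5)
})

test_that("uniform HR sampling is statistically uniform", {
  ds <- gen_dataset(synth_config(n_samples = 1000, hr_range = c(60, 120),
                                 seed = 7))
  hrs <- ds$manifest$hr
  # realized window HR sits within ~1.5 bpm of the drawn range
  expect_true(all(hrs >= 58.5 & hrs <= 121.5))
  ct <- table(cut(pmin(pmax(hrs, 60.01), 119.99), seq(60, 120, by = 10)))
  p <- chisq.test(ct)$p.value
  expect_gt(p, 0.01)
})

test_that("imbalanced HR sampling concentrates mass as configured", {
  cfg <- synth_config(n_samples = 1000, hr_distribution = "imbalanced",
                      seed = 8)
  ds <- gen_dataset(cfg)
  frac <- mean(ds$manifest$hr >= 60 & ds$manifest$hr <= 80)
  # binomial 99% interval around 0.9 at n = 1000
  expect_gt(frac, 0.9 - 2.58 * sqrt(0.9 * 0.1 / 1000))
  expect_lt(frac, 0.9 + 2.58 * sqrt(0.9 * 0.1 / 1000))
})

test_that("dataset write/read round-trips bit-exactly", {
  ds <- gen_dataset(synth_config(n_samples = 3, seed = 9))
  dir <- tempfile()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_identical(back$samples[[2]]$stmap$values,
                   ds$samples[[2]]$stmap$values)
  expect_equal(back$manifest$hr, ds$manifest$hr)
})

test_that("noiseless pipeline bypass recovers the generator HR (end-to-end)", {
  # preprocess -> band decomposition -> strongest band -> spectral HR,
  # without any trained network in the loop
  cfg <- synth_config(drift_amp = 0, artifact_rate = 0, snr_db = Inf,
                      seed = 10)
  for (idx in 1:5) {
    s <- gen_sample(cfg, idx)
    m <- preprocess_stmap(s$stmap)
    stack <- decompose_multiband(m)
    band_power <- apply(stack$values, 1, function(v) sum(v^2))
    strongest <- which.max(band_power)
    bypass <- rowMeans(stack$values[strongest, , , 1])  # luma channel mean
    hr <- hr_from_bvp(bypass, fps = 30)$hr_bpm
    expect_lt(abs(hr - s$gt_hr), 2)
  }
})
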