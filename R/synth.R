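# Seeded synthetic rPPG generator: quasi-periodic pulse waveforms with
# beat-to-beat LF/HF modulation, per-region pulsatile gains, slow
# illumination drift, transient motion artifacts and white noise — the
# disturbance structure the recovery pipeline is designed to suppress.

#' Synthetic-data configuration
#'
#' Defaults emulate the study conditions of the pipeline: 15 s windows at
#' 30 fps (450 frames), four facial regions, heart rates 50-150 bpm, pulse
#' waveform with three harmonics, LF/HF beat-interval modulation, sub-0.15 Hz
#' illumination drift, sparse motion transients and 10 dB white noise.
#'
#' @param n_samples number of windows to generate
#' @param duration_s window length in seconds
#' @param fps frame rate (Hz)
#' @param hr_range length-2 range of heart rates (bpm), within 40-180
#' @param hr_distribution `"uniform"` or `"imbalanced"`
#' @param hr_weights for `"imbalanced"`: data.frame-like list with `lo`,
#'   `hi` (bpm) and `weight` columns describing the sampling mixture
#' @param lf_freq,hf_freq modulation frequencies of the beat interval (Hz)
#' @param lf_depth,hf_depth relative modulation depths (0 disables)
#' @param harmonic_amps amplitudes of the pulse harmonics
#' @param pulse_skew systolic-upstroke sharpening (phase-warp amount, 0-0.5)
#' @param region_gains `4 x 3` matrix of per-region/per-channel pulsatile
#'   gains (intensity units per unit BVP); defaults make green strongest and
#'   the forehead/cheeks more perfused than the chin
#' @param baseline length-3 RGB baseline intensities (0-255 scale)
#' @param drift_amp illumination-drift amplitude (intensity units; 0 disables)
#' @param drift_cutoff drift bandwidth (Hz)
#' @param artifact_rate expected motion transients per window (0 disables)
#' @param artifact_amp transient amplitude (intensity units)
#' @param artifact_dur transient duration (s)
#' @param interference_freq frequency (Hz) of an optional common-mode
#'   narrowband interferer (e.g. flickering illumination); 0 disables
#' @param interference_amp amplitude of the interferer (intensity units)
#' @param snr_db per-trace white-noise SNR in dB (`Inf` disables)
#' @param seed root seed; each sample derives its own stream from it
#' @return an object of class `synth_config`
#' @export
synth_config <- function(n_samples = 100L, duration_s = 15, fps = 30,
                         hr_range = c(50, 150),
                         hr_distribution = c("uniform", "imbalanced"),
                         hr_weights = NULL,
                         lf_freq = 0.1, hf_freq = 0.3,
                         lf_depth = 0.03, hf_depth = 0.02,
                         harmonic_amps = c(1.0, 0.4, 0.15),
                         pulse_skew = 0.2,
                         region_gains = NULL,
                         baseline = c(150, 110, 95),
                         drift_amp = 2.0, drift_cutoff = 0.15,
                         artifact_rate = 1.0, artifact_amp = 5.0,
                         artifact_dur = 0.5,
                         interference_freq = 0, interference_amp = 0,
                         snr_db = 10, seed = 1L) {
  hr_distribution <- match.arg(hr_distribution)
  assert_that(hr_range[1] >= 40 && hr_range[2] <= 180 &&
                hr_range[1] < hr_range[2],
              "hr_range must lie within [40, 180]")
  assert_that(all(harmonic_amps >= 0) && drift_amp >= 0 &&
                artifact_amp >= 0 && artifact_rate >= 0,
              "amplitudes and rates must be >= 0")
  if (is.null(region_gains)) {
    channel_gain <- c(0.5, 1.0, 0.35)            # R, G, B pulsatility
    region_strength <- c(1.0, 0.9, 0.9, 0.7)     # forehead, cheeks, chin
    region_gains <- outer(region_strength, channel_gain)
  }
  region_gains <- matrix(region_gains, ncol = 3)
  if (hr_distribution == "imbalanced" && is.null(hr_weights))
    hr_weights <- list(lo = c(60, 100), hi = c(80, 140), weight = c(0.9, 0.1))
  structure(list(n_samples = as.integer(n_samples), duration_s = duration_s,
                 fps = fps, hr_range = hr_range,
                 hr_distribution = hr_distribution, hr_weights = hr_weights,
                 lf_freq = lf_freq, hf_freq = hf_freq,
                 lf_depth = lf_depth, hf_depth = hf_depth,
                 harmonic_amps = harmonic_amps, pulse_skew = pulse_skew,
                 region_gains = region_gains, baseline = baseline,
                 drift_amp = drift_amp, drift_cutoff = drift_cutoff,
                 artifact_rate = artifact_rate, artifact_amp = artifact_amp,
                 artifact_dur = artifact_dur,
                 interference_freq = interference_freq,
                 interference_amp = interference_amp, snr_db = snr_db,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a pulse waveform with ground-truth beat intervals
#'
#' The instantaneous beat frequency is `hr/60` modulated multiplicatively by
#' LF and HF sinusoids; its integral gives the cardiac phase, and the
#' waveform is a sum of harmonics of that phase with a phase-warp that
#' sharpens the systolic upstroke while keeping the systolic peaks exactly at
#' phase multiples of 2*pi. Beat times are the (linearly interpolated) phase
#' crossings of 2*pi*k.
#'
#' @param hr target mean heart rate (bpm)
#' @param duration_s,fps window length (s) and frame rate (Hz)
#' @param lf_freq,hf_freq,lf_depth,hf_depth modulation settings
#' @param harmonic_amps harmonic amplitudes
#' @param pulse_skew upstroke sharpening in `[0, 0.5]`
#' @param seed integer seed (draws the modulation phases)
#' @return list with `bvp` (numeric vector), `ibi` (an [ibi_series()]) and
#'   `phase`
#' @export
gen_bvp_waveform <- function(hr, duration_s = 15, fps = 30,
                             lf_freq = 0.1, hf_freq = 0.3,
                             lf_depth = 0.03, hf_depth = 0.02,
                             harmonic_amps = c(1.0, 0.4, 0.15),
                             pulse_skew = 0.2, seed = 1L) {
  n <- round(duration_s * fps)
  tt <- (seq_len(n) - 1) / fps
  set.seed(seed)
  ph_lf <- stats::runif(1, 0, 2 * pi)
  ph_hf <- stats::runif(1, 0, 2 * pi)
  f_inst <- (hr / 60) * (1 + lf_depth * sin(2 * pi * lf_freq * tt + ph_lf) +
                           hf_depth * sin(2 * pi * hf_freq * tt + ph_hf))
  phase <- 2 * pi * cumsum(f_inst) / fps
  phase <- phase - phase[1]
  warped <- phase + pulse_skew * sin(phase)
  bvp <- numeric(n)
  for (h in seq_along(harmonic_amps))
    bvp <- bvp + harmonic_amps[h] * cos(h * warped)
  # beat times: crossings of phase = 2*pi*k (peaks of the harmonic sum)
  kmax <- floor(phase[n] / (2 * pi))
  beats <- numeric(0)
  if (kmax >= 1) {
    targets <- 2 * pi * seq_len(kmax)
    idx <- findInterval(targets, phase)
    beats <- vapply(seq_along(targets), function(j) {
      i <- idx[j]
      frac <- (targets[j] - phase[i]) / (phase[i + 1] - phase[i])
      (i - 1 + frac) / fps
    }, numeric(1))
  }
  beats <- c(0, beats)   # the window starts on a systolic peak (phase 0)
  list(bvp = bvp, ibi = ibi_series(diff(beats), beats), phase = phase)
}

#' Render a pulse waveform into a region-mean RGB series
#'
#' Each region-channel trace is `baseline + gain * bvp + drift + artifacts +
#' white noise`. Drift is a sum of sub-cutoff sinusoids; artifacts are
#' half-sine transients hitting all channels of one region at once; noise is
#' white Gaussian at `snr_db` relative to the per-trace pulsatile power.
#'
#' @param bvp numeric pulse waveform
#' @param cfg a [synth_config()]
#' @param seed integer seed
#' @param return_parts also return the noise-free signal component (for
#'   diagnostics)
#' @return an [rgb_region_series()] (with attribute `parts` when requested)
#' @export
gen_stmap <- function(bvp, cfg = synth_config(), seed = 1L,
                      return_parts = FALSE) {
  n <- length(bvp)
  nI <- nrow(cfg$region_gains)
  tt <- (seq_len(n) - 1) / cfg$fps
  set.seed(seed)
  vals <- array(0, c(n, nI, 3))
  pure <- array(0, c(n, nI, 3))
  # region-wide artifact transients
  n_art <- stats::rpois(1, cfg$artifact_rate)
  art <- matrix(0, n, nI)
  if (n_art > 0 && cfg$artifact_amp > 0) {
    for (a in seq_len(n_art)) {
      reg <- sample.int(nI, 1)
      t0 <- stats::runif(1, 0, max(1e-9, cfg$duration_s - cfg$artifact_dur))
      inside <- tt >= t0 & tt < t0 + cfg$artifact_dur
      art[inside, reg] <- art[inside, reg] +
        cfg$artifact_amp * sin(pi * (tt[inside] - t0) / cfg$artifact_dur)
    }
  }
  interf <- numeric(n)
  if (cfg$interference_freq > 0 && cfg$interference_amp > 0)
    interf <- cfg$interference_amp *
      sin(2 * pi * cfg$interference_freq * tt + stats::runif(1, 0, 2 * pi))
  for (i in seq_len(nI)) for (c in 1:3) {
    sig <- cfg$region_gains[i, c] * bvp
    drift <- numeric(n)
    if (cfg$drift_amp > 0) {
      for (d in 1:3) {
        fd <- stats::runif(1, 0.01, cfg$drift_cutoff)
        drift <- drift + (cfg$drift_amp / 3) *
          sin(2 * pi * fd * tt + stats::runif(1, 0, 2 * pi))
      }
    }
    noise <- numeric(n)
    if (is.finite(cfg$snr_db)) {
      sig_pow <- mean((sig - mean(sig))^2)
      noise <- stats::rnorm(n, sd = sqrt(sig_pow / 10^(cfg$snr_db / 10)))
    }
    pure[, i, c] <- cfg$baseline[c] + sig
    vals[, i, c] <- cfg$baseline[c] + sig + drift + art[, i] + interf + noise
  }
  out <- rgb_region_series(vals, fps = cfg$fps,
                           region_labels = c("forehead", "left_cheek",
                                             "right_cheek", "chin")[seq_len(nI)])
  if (return_parts) attr(out, "parts") <- list(pure = pure)
  out
}

#' Generate one synthetic sample by index
#'
#' Bit-exactly regenerable from `(cfg, index)`: the sample's seed derives
#' from the root seed and the index only.
#'
#' @param cfg a [synth_config()]
#' @param index sample index (1-based)
#' @return a `synth_sample`: list with `stmap` ([rgb_region_series()]),
#'   `gt_bvp`, `gt_hr` (bpm), `gt_ibi` ([ibi_series()]) and `seed`
#' @export
gen_sample <- function(cfg, index) {
  sd0 <- derive_seed(cfg$seed, index)
  set.seed(sd0)
  hr <- if (cfg$hr_distribution == "uniform") {
    stats::runif(1, cfg$hr_range[1], cfg$hr_range[2])
  } else {
    w <- cfg$hr_weights
    j <- sample.int(length(w$weight), 1, prob = w$weight)
    stats::runif(1, w$lo[j], w$hi[j])
  }
  wave <- gen_bvp_waveform(hr, cfg$duration_s, cfg$fps,
                           cfg$lf_freq, cfg$hf_freq,
                           cfg$lf_depth, cfg$hf_depth,
                           cfg$harmonic_amps, cfg$pulse_skew,
                           seed = derive_seed(sd0, 1L))
  stm <- gen_stmap(wave$bvp, cfg, seed = derive_seed(sd0, 2L))
  # record the realized window HR (modulation shifts it slightly off the draw)
  hr <- 60 / mean(wave$ibi$intervals)
  structure(list(stmap = stm, gt_bvp = wave$bvp, gt_hr = hr,
                 gt_ibi = wave$ibi, seed = sd0, index = index),
            class = "synth_sample")
}

#' Generate a synthetic dataset with manifest
#'
#' @param cfg a [synth_config()]
#' @return list with `samples` (list of `synth_sample`) and `manifest`
#'   (data.frame: index, hr, seed)
#' @export
gen_dataset <- function(cfg = synth_config()) {
  samples <- lapply(seq_len(cfg$n_samples), function(i) gen_sample(cfg, i))
  manifest <- data.frame(
    index = vapply(samples, `[[`, numeric(1), "index"),
    hr = vapply(samples, `[[`, numeric(1), "gt_hr"),
    seed = vapply(samples, `[[`, numeric(1), "seed"))
  list(samples = samples, manifest = manifest)
}

# turn a synthetic sample into a training record (preprocess + targets);
# ground truth is standardized so the Pearson loss sees a zero-mean target
synth_to_record <- function(sample, pre_cfg = preprocess_config(),
                            augment = FALSE) {
  m <- preprocess_stmap(sample$stmap,
                        preprocess_config(noise_snr_db = pre_cfg$noise_snr_db,
                                          tdn_window = pre_cfg$tdn_window,
                                          rng_seed = derive_seed(
                                            pre_cfg$rng_seed, sample$index)),
                        augment = augment)
  sample_record(m, zscore_trace(sample$gt_bvp), sample$gt_hr)
}
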