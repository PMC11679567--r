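# Heart rate and heart rate variability from a recovered BVP waveform, plus
# the evaluation metrics (MAE, RMSE, Std of the error, Pearson r).

#' Heart rate from the BVP power spectrum
#'
#' The headline HR is read off in one pass as the frequency of the Welch
#' power-spectrum maximum within the physiological band, converted to bpm.
#' The zero-padded spectrum gives sub-bin peak placement well below 1 bpm at
#' 15 s / 30 fps.
#'
#' @param bvp a [bvp_signal()] (or numeric vector with `fps` supplied)
#' @param band length-2 numeric search band in Hz (default 0.6-4.2 Hz,
#'   i.e. 36-252 bpm)
#' @param fps sampling rate, required when `bvp` is a bare vector
#' @return list with `hr_bpm`, `method = "spectral"` and `confidence` (peak
#'   power as a fraction of in-band power)
#' @export
hr_from_bvp <- function(bvp, band = c(0.6, 4.2), fps = NULL) {
  if (inherits(bvp, "bvp_signal")) {
    x <- bvp$values
    fps <- bvp$fps
  } else {
    x <- as.numeric(bvp)
    assert_that(!is.null(fps), "fps must be given for a bare vector")
  }
  assert_that(length(x) >= 256, "need at least 256 samples for spectral HR")
  ps <- welch_psd(x, fs = fps, nperseg = min(length(x), 300L), nfft = 8192L)
  sel <- ps$freq >= band[1] & ps$freq <= band[2]
  pw <- ps$power[sel]
  if (!any(pw > 0)) stopf("power spectrum is zero in the %g-%g Hz band",
                          band[1], band[2])
  i <- which.max(pw)
  hr <- 60 * ps$freq[sel][i]
  list(hr_bpm = hr, method = "spectral",
       confidence = pw[i] / sum(pw))
}

#' Inter-beat interval series
#'
#' @param intervals numeric vector of IBIs in seconds (already gated)
#' @param peak_times numeric vector of peak times in seconds
#' @return object of class `ibi_series`
#' @export
ibi_series <- function(intervals, peak_times) {
  structure(list(intervals = as.numeric(intervals),
                 peak_times = as.numeric(peak_times)),
            class = "ibi_series")
}

# zero-phase Butterworth band-pass
#' Band-pass filter a BVP trace (zero-phase Butterworth)
#' @param x numeric vector
#' @param fps sampling rate (Hz)
#' @param band length-2 numeric pass band in Hz
#' @param order filter order
#' @return filtered vector
#' @export
bandpass_bvp <- function(x, fps, band = c(0.6, 4.2), order = 3L) {
  bf <- signal::butter(order, band / (fps / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Detect systolic peaks and extract inter-beat intervals
#'
#' Local maxima with a minimum spacing of 0.25 s and an adaptive height
#' threshold (a fraction of the largest peak above the signal median) are
#' taken as systolic peaks; peak times are refined by parabolic interpolation
#' for sub-frame resolution. Intervals outside the physiological 0.25-2.0 s
#' gate are dropped (and reported).
#'
#' @param bvp a [bvp_signal()] or numeric vector (band-passed to the
#'   physiological range; use [bandpass_bvp()] first for raw traces)
#' @param fps sampling rate, required for a bare vector
#' @param min_rel_height adaptive threshold as a fraction of the largest
#'   peak-to-median excursion
#' @return an [ibi_series()]
#' @export
detect_peaks <- function(bvp, fps = NULL, min_rel_height = 0.3) {
  if (inherits(bvp, "bvp_signal")) {
    x <- bvp$values
    fps <- bvp$fps
  } else {
    x <- as.numeric(bvp)
    assert_that(!is.null(fps), "fps must be given for a bare vector")
  }
  if (pop_sd(x) == 0) stopf("flat signal: no peaks")
  mindist <- max(1L, round(0.25 * fps))
  n <- length(x)
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(cand) < 3) stopf("fewer than 3 peaks detected")
  # greedy min-distance suppression, strongest peaks first
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep_idx <- integer(0)
  for (i in cand)
    if (!length(keep_idx) || all(abs(keep_idx - i) >= mindist))
      keep_idx <- c(keep_idx, i)
  med <- stats::median(x)
  thr <- med + min_rel_height * (max(x[keep_idx]) - med)
  loc <- sort(keep_idx[x[keep_idx] >= thr])
  if (length(loc) < 3) stopf("fewer than 3 peaks above the adaptive threshold")
  # parabolic refinement of each peak position
  times <- vapply(loc, function(i) {
    if (i <= 1 || i >= length(x)) return((i - 1) / fps)
    y1 <- x[i - 1]; y2 <- x[i]; y3 <- x[i + 1]
    den <- y1 - 2 * y2 + y3
    delta <- if (abs(den) > 1e-12) 0.5 * (y1 - y3) / den else 0
    (i - 1 + max(-0.5, min(0.5, delta))) / fps
  }, numeric(1))
  ibis <- diff(times)
  keep <- ibis > 0.25 & ibis < 2.0
  if (any(!keep))
    message(sprintf("detect_peaks: dropped %d interval(s) outside 0.25-2.0 s",
                    sum(!keep)))
  ibi_series(ibis[keep], times)
}

#' LF/HF heart rate variability in normalized units
#'
#' The IBI series is interpolated to a uniform 4 Hz tachogram (cubic spline),
#' linearly detrended, and its Welch power spectrum is integrated over the
#' standard LF (0.04-0.15 Hz) and HF (0.15-0.4 Hz) bands. Results are
#' normalized units: `lf_nu = LF / (LF + HF)`, `hf_nu = HF / (LF + HF)`,
#' plus the LF/HF ratio.
#'
#' @param ibi an [ibi_series()]
#' @param lf_band,hf_band numeric length-2 band edges in Hz
#' @return list with `lf_nu`, `hf_nu`, `lf_hf_ratio`
#' @export
hrv_lf_hf <- function(ibi, lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.4)) {
  assert_that(inherits(ibi, "ibi_series"), "ibi must be an ibi_series")
  assert_that(length(ibi$intervals) >= 2, "need at least 2 intervals")
  tt <- ibi$peak_times[-1]          # each interval stamped at its end beat
  tt <- tt[seq_along(ibi$intervals)]
  span <- max(tt) - min(tt)
  assert_that(span >= 10, "IBI series must span at least 10 s (got %.1f s)",
              span)
  fs <- 4
  grid <- seq(min(tt), max(tt), by = 1 / fs)
  tach <- stats::spline(tt, ibi$intervals, xout = grid, method = "fmm")$y
  tach <- stats::residuals(stats::lm(tach ~ grid))   # linear detrend
  ps <- welch_psd(tach, fs = fs, nperseg = max(60L, min(length(tach), 240L)),
                  nfft = 4096L)
  lf <- sum(ps$power[ps$freq >= lf_band[1] & ps$freq < lf_band[2]])
  hf <- sum(ps$power[ps$freq >= hf_band[1] & ps$freq < hf_band[2]])
  if (lf + hf <= 0) stopf("no spectral power in the LF + HF bands")
  list(lf_nu = lf / (lf + hf), hf_nu = hf / (lf + hf),
       lf_hf_ratio = lf / hf)
}

#' Agreement metrics between predicted and reference values
#'
#' @param pred,truth numeric vectors of equal length >= 2
#' @return list with `MAE`, `RMSE`, `Std` (population standard deviation of
#'   the error) and `r` (Pearson correlation; `NaN` with a warning when
#'   either input is constant)
#' @export
error_metrics <- function(pred, truth) {
  assert_that(length(pred) == length(truth), "length mismatch")
  assert_that(length(pred) >= 2, "need at least 2 values")
  e <- pred - truth
  r <- if (pop_sd(pred) == 0 || pop_sd(truth) == 0) {
    warning("constant input: Pearson r undefined")
    NaN
  } else {
    stats::cor(pred, truth)
  }
  list(MAE = mean(abs(e)), RMSE = sqrt(mean(e^2)), Std = pop_sd(e), r = r)
}
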