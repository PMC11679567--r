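# Spatio-temporal map preprocessing: region-mean RGB series -> normalized
# modified-YUV maps, plus training-time white-noise augmentation.

# Modified-YUV color rotation. Row sums are (1, 0, 0): a grey level maps to
# pure luma, so illumination common to all channels lands in Y.
MYUV_MATRIX <- matrix(c(
   0.299,  0.587,  0.114,
  -0.169, -0.331,  0.5,
   0.5,   -0.419, -0.081
), nrow = 3, byrow = TRUE,
  dimnames = list(c("Y", "U", "V"), c("R", "G", "B")))

#' Region-mean RGB time series
#'
#' Container for the per-frame mean pixel value of each facial region, the
#' compact video representation consumed by the rest of the pipeline.
#'
#' @param values numeric array `T x I x 3` (time x region x RGB), finite
#' @param fps frames per second (Hz), > 0
#' @param region_labels optional character vector of length `I`
#' @return an object of class `rgb_region_series`
#' @export
rgb_region_series <- function(values, fps,
                              region_labels = NULL) {
  assert_that(is.array(values) && length(dim(values)) == 3,
              "values must be a T x I x 3 array")
  d <- dim(values)
  assert_that(d[1] >= 2, "need at least 2 frames, got %d", d[1])
  assert_that(d[2] >= 1, "need at least 1 region")
  assert_that(d[3] == 3, "third dimension must hold 3 color channels")
  assert_finite(values, "region series")
  assert_that(is.numeric(fps) && length(fps) == 1 && fps > 0,
              "fps must be a positive scalar")
  if (is.null(region_labels)) region_labels <- paste0("region", seq_len(d[2]))
  assert_that(length(region_labels) == d[2],
              "region_labels must have one entry per region")
  structure(list(values = values, fps = fps, region_labels = region_labels),
            class = "rgb_region_series")
}

#' Spatio-temporal map in modified-YUV space
#'
#' @param values numeric array `T x I x 3` (time x region x YUV)
#' @param fps frames per second (Hz)
#' @param normalized logical; whether temporal normalization was applied
#' @param region_labels optional labels
#' @return an object of class `stmap`
#' @export
stmap <- function(values, fps, normalized = FALSE, region_labels = NULL) {
  d <- dim(values)
  assert_that(length(d) == 3 && d[3] == 3, "values must be T x I x 3")
  assert_finite(values, "spatio-temporal map")
  if (is.null(region_labels)) region_labels <- paste0("region", seq_len(d[2]))
  structure(list(values = values, fps = fps, normalized = isTRUE(normalized),
                 region_labels = region_labels),
            class = "stmap")
}

#' Preprocessing configuration
#'
#' @param noise_snr_db per-trace signal-to-noise ratio (dB) of the white-noise
#'   augmentation; `Inf` disables it. Default 10 dB.
#' @param tdn_window temporal-normalization window in samples; 0 normalizes
#'   over the whole record, otherwise a centered sliding window of at least 8
#'   samples is used (followed by a global re-standardization).
#' @param rng_seed integer seed for the noise stream
#' @return an object of class `preprocess_config`
#' @export
preprocess_config <- function(noise_snr_db = 10, tdn_window = 0L,
                              rng_seed = 1L) {
  assert_that(is.numeric(noise_snr_db) && length(noise_snr_db) == 1 &&
                !is.na(noise_snr_db),
              "noise_snr_db must be a numeric scalar (Inf disables noise)")
  tdn_window <- as.integer(tdn_window)
  assert_that(tdn_window == 0L || tdn_window >= 8L,
              "tdn_window must be 0 (whole record) or >= 8 samples")
  structure(list(noise_snr_db = noise_snr_db, tdn_window = tdn_window,
                 rng_seed = as.integer(rng_seed)),
            class = "preprocess_config")
}

#' Convert region-mean RGB to modified YUV
#'
#' Applies the fixed luma/chroma rotation that concentrates the pulse-carrying
#' brightness variation in the Y channel while the U/V chroma channels absorb
#' color-balance differences across the face. The map is exactly linear.
#'
#' @param series an [rgb_region_series()]
#' @return an un-normalized [stmap()] of identical shape
#' @export
rgb_to_modified_yuv <- function(series) {
  assert_that(inherits(series, "rgb_region_series"),
              "series must be an rgb_region_series")
  v <- series$values
  d <- dim(v)
  flat <- matrix(aperm(v, c(3, 1, 2)), nrow = 3)   # 3 x (T*I)
  yuv <- MYUV_MATRIX %*% flat
  out <- aperm(array(yuv, c(3, d[1], d[2])), c(2, 3, 1))
  stmap(out, fps = series$fps, normalized = FALSE,
        region_labels = series$region_labels)
}

# z-score a single trace with population sd; constant traces collapse to 0.
zscore_trace <- function(x) {
  s <- pop_sd(x)
  if (s < .Machine$double.eps * max(1, abs(mean(x)))) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# centered sliding-window standardization via cumulative sums
zscore_sliding <- function(x, w) {
  n <- length(x)
  w <- min(w, n)
  half <- w %/% 2
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  cnt <- hi - lo + 1
  m <- (cs[hi + 1] - cs[lo]) / cnt
  v <- (cs2[hi + 1] - cs2[lo]) / cnt - m^2
  s <- sqrt(pmax(v, 0))
  out <- ifelse(s > 1e-12, (x - m) / s, 0)
  out
}

#' Temporal normalization of a spatio-temporal map
#'
#' Standardizes every region-channel trace to zero mean and unit (population)
#' variance. With `tdn_window = 0` the whole record is standardized in one
#' pass; otherwise a centered sliding window removes local mean and scale and
#' the result is re-standardized globally so that the unit-variance contract
#' holds either way. Constant traces are returned as all zeros rather than
#' dividing by a vanishing scale.
#'
#' @param map an un-normalized [stmap()]
#' @param cfg a [preprocess_config()]
#' @return a normalized [stmap()]
#' @export
temporal_normalize <- function(map, cfg = preprocess_config()) {
  assert_that(inherits(map, "stmap"), "map must be an stmap")
  v <- map$values
  d <- dim(v)
  degenerate <- character(0)
  for (i in seq_len(d[2])) for (c in seq_len(d[3])) {
    tr <- v[, i, c]
    if (pop_sd(tr) < .Machine$double.eps * max(1, abs(mean(tr)))) {
      v[, i, c] <- 0
      degenerate <- c(degenerate, sprintf("region %d channel %d", i, c))
      next
    }
    if (cfg$tdn_window > 0L) tr <- zscore_sliding(tr, cfg$tdn_window)
    v[, i, c] <- zscore_trace(tr)
  }
  if (length(degenerate) > 0)
    message("temporal_normalize: constant trace(s) set to zero: ",
            paste(degenerate, collapse = ", "))
  stmap(v, fps = map$fps, normalized = TRUE, region_labels = map$region_labels)
}

#' Add white-noise augmentation to a normalized map
#'
#' Adds zero-mean Gaussian noise to every region-channel trace, scaled so the
#' per-trace signal-to-noise ratio equals `cfg$noise_snr_db`. Used during
#' training to emulate residual illumination/motion disturbances.
#' `noise_snr_db = Inf` is the disabled sentinel. Deterministic under
#' `cfg$rng_seed`.
#'
#' @param map a normalized [stmap()]
#' @param cfg a [preprocess_config()]
#' @return an [stmap()] with noise added
#' @export
inject_white_noise <- function(map, cfg = preprocess_config()) {
  assert_that(inherits(map, "stmap"), "map must be an stmap")
  assert_that(map$normalized, "inject_white_noise expects a normalized map")
  if (is.infinite(cfg$noise_snr_db)) return(map)
  v <- map$values
  d <- dim(v)
  set.seed(cfg$rng_seed)
  for (i in seq_len(d[2])) for (c in seq_len(d[3])) {
    tr <- v[, i, c]
    sig_var <- mean((tr - mean(tr))^2)
    noise_sd <- sqrt(sig_var / 10^(cfg$noise_snr_db / 10))
    v[, i, c] <- tr + stats::rnorm(d[1], sd = noise_sd)
  }
  stmap(v, fps = map$fps, normalized = TRUE, region_labels = map$region_labels)
}

#' Preprocess a region series end to end
#'
#' Convenience wrapper: modified-YUV conversion, temporal normalization and
#' (optionally, when `augment = TRUE`) white-noise augmentation.
#'
#' @param series an [rgb_region_series()]
#' @param cfg a [preprocess_config()]
#' @param augment add training-time white noise?
#' @return a normalized [stmap()]
#' @export
preprocess_stmap <- function(series, cfg = preprocess_config(),
                             augment = FALSE) {
  m <- temporal_normalize(rgb_to_modified_yuv(series), cfg)
  if (augment) m <- inject_white_noise(m, cfg) else m
}

#' Extract a region-mean series from decoded video frames
#'
#' Face-landmark detection is delegated to an external backend: this operation
#' consumes frames that are already decoded to an array plus, per frame, the
#' pixel masks of the facial regions (forehead, left cheek, right cheek, chin
#' in the default layout). A frame whose masks are `NULL` counts as a
#' detection dropout: the previous frame's region means are carried forward
#' and the event is reported. If no frame has a detection the call fails.
#'
#' @param frames numeric array `T x H x W x 3` of decoded RGB frames
#' @param masks list of length `T`; element t is a list of `I` logical
#'   `H x W` masks, or `NULL` for a detection dropout
#' @param fps frames per second
#' @param region_labels optional labels for the `I` regions
#' @return an [rgb_region_series()]
#' @export
video_to_region_series <- function(frames, masks, fps, region_labels = NULL) {
  assert_that(is.array(frames) && length(dim(frames)) == 4 &&
                dim(frames)[4] == 3, "frames must be a T x H x W x 3 array")
  nT <- dim(frames)[1]
  assert_that(length(masks) == nT, "need one mask set (or NULL) per frame")
  detected <- !vapply(masks, is.null, logical(1))
  assert_that(any(detected), "no frame has a detected face")
  nI <- length(masks[[which(detected)[1]]])
  vals <- array(NA_real_, c(nT, nI, 3))
  dropouts <- 0L
  last <- NULL
  for (t in seq_len(nT)) {
    if (is.null(masks[[t]])) {
      dropouts <- dropouts + 1L
      if (!is.null(last)) vals[t, , ] <- last
      next
    }
    cur <- matrix(NA_real_, nI, 3)
    for (i in seq_len(nI)) {
      m <- masks[[t]][[i]]
      for (c in 1:3) cur[i, c] <- mean(frames[t, , , c][m])
    }
    vals[t, , ] <- cur
    last <- cur
  }
  # leading dropouts (before the first detection) back-fill from it
  first <- which(detected)[1]
  if (first > 1) for (t in seq_len(first - 1)) vals[t, , ] <- vals[first, , ]
  if (dropouts > 0)
    message(sprintf("video_to_region_series: %d dropout frame(s) carried forward",
                    dropouts))
  rgb_region_series(vals, fps = fps, region_labels = region_labels)
}
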