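# Multi-band decomposition: orthonormal DCT, in-place spectrum masking, IDCT.
#
# Each region-channel trace of the spatio-temporal map is treated as a raw
# pulse signal; cutting its DCT spectrum into disjoint frequency bands yields
# K band-limited versions, each carrying one "mode" of the signal (pulse
# fundamental, harmonics, residual noise) for the per-band network branches.

#' Orthonormal type-II DCT of a trace
#'
#' Computed via an FFT of the even-odd permuted sequence (length-N transform,
#' no 2N padding), then scaled to the orthonormal convention so that the
#' transform is an isometry: `sum(coeffs^2) == sum(x^2)`.
#'
#' @param x numeric vector, length >= 2
#' @return numeric vector of DCT coefficients, same length
#' @export
dct_ortho <- function(x) {
  n <- length(x)
  assert_that(n >= 2, "dct_ortho needs at least 2 samples")
  assert_finite(x, "dct input")
  v <- c(x[seq(1, n, by = 2)], rev(x[seq(2, n, by = 2)]))
  k <- 0:(n - 1)
  ph <- exp(-1i * pi * k / (2 * n))
  raw <- Re(ph * stats::fft(v))            # unnormalized DCT-II (half scale)
  scale <- c(sqrt(1 / n), rep(sqrt(2 / n), n - 1))
  raw * scale
}

#' Orthonormal type-III (inverse) DCT
#'
#' Exact inverse of [dct_ortho()]: `idct_ortho(dct_ortho(x))` recovers `x` to
#' round-off.
#'
#' @param coeffs numeric vector of orthonormal DCT-II coefficients
#' @return numeric vector, the time-domain trace
#' @export
idct_ortho <- function(coeffs) {
  n <- length(coeffs)
  assert_that(n >= 2, "idct_ortho needs at least 2 coefficients")
  assert_finite(coeffs, "idct input")
  scale <- c(sqrt(1 / n), rep(sqrt(2 / n), n - 1))
  raw <- coeffs / scale                    # back to unnormalized convention
  k <- 0:(n - 1)
  ph <- exp(1i * pi * k / (2 * n))
  # undo raw = Re(conj-phase * fft(v)): rebuild the complex fft(v) using the
  # conjugate-symmetry of the real sequence v, then invert the permutation
  w <- ph * (raw - 1i * c(0, rev(raw[-1])))
  v <- Re(stats::fft(w, inverse = TRUE)) / n
  x <- numeric(n)
  n_even <- ceiling(n / 2)
  x[seq(1, n, by = 2)] <- v[seq_len(n_even)]
  if (n > 1) x[seq(2, n, by = 2)] <- rev(v[(n_even + 1):n])
  x
}

#' Frequencies of the DCT bins
#'
#' Bin `u` (0-based) of a length-`T` DCT at sampling rate `fps` represents
#' frequency `u * fps / (2 T)` Hz.
#'
#' @param n trace length
#' @param fps sampling rate (Hz)
#' @return numeric vector of `n` bin frequencies
#' @export
dct_bin_freqs <- function(n, fps) (0:(n - 1)) * fps / (2 * n)

#' Frequency band specification
#'
#' `K` disjoint, sorted, half-open intervals `[lo, hi)` in Hz. The defaults
#' split the physiological range into a fundamental band (36-90 bpm), a
#' band covering fast fundamentals plus first harmonics (90-180 bpm), and a
#' harmonic/high band, so each network branch sees one signal mode.
#'
#' @param bands numeric matrix `K x 2` of `[lo, hi)` bounds in Hz, or a list
#'   of length-2 vectors
#' @param fps sampling rate the bands refer to (Hz)
#' @return an object of class `band_spec`
#' @export
band_spec <- function(bands = rbind(c(0.6, 1.5), c(1.5, 3.0), c(3.0, 4.2)),
                      fps = 30) {
  if (is.list(bands)) bands <- do.call(rbind, bands)
  bands <- matrix(as.numeric(bands), ncol = 2)
  K <- nrow(bands)
  assert_that(K >= 1, "need at least one band")
  assert_that(all(bands[, 1] >= 0) && all(bands[, 1] < bands[, 2]),
              "each band must satisfy 0 <= lo < hi")
  assert_that(all(bands[, 2] <= fps / 2),
              "band upper edges must not exceed the Nyquist frequency %g",
              fps / 2)
  if (K > 1) {
    assert_that(all(diff(bands[, 1]) > 0), "bands must be sorted by lo")
    assert_that(all(bands[-K, 2] <= bands[-1, 1]),
                "bands must be non-overlapping")
  }
  structure(list(bands = bands, fps = fps, K = K), class = "band_spec")
}

#' Keep one frequency band of a DCT spectrum, zeroing the rest
#'
#' Coefficients whose bin frequency lies in `[lo, hi)` are kept in place; all
#' others are set to zero (zero-padding in place, no spectrum compaction), so
#' the masked spectrum inverts back to a trace of the original length.
#'
#' @param coeffs DCT coefficient vector
#' @param band length-2 numeric `[lo, hi)` in Hz
#' @param fps sampling rate (Hz)
#' @return masked coefficient vector
#' @export
band_slice_zero_pad <- function(coeffs, band, fps) {
  f <- dct_bin_freqs(length(coeffs), fps)
  keep <- f >= band[1] & f < band[2]
  if (!any(keep))
    stopf("band [%g, %g) Hz contains no DCT bin at T = %d, fps = %g",
          band[1], band[2], length(coeffs), fps)
  out <- numeric(length(coeffs))
  out[keep] <- coeffs[keep]
  out
}

#' Multi-band stack
#'
#' The `K` band-limited versions of every region-channel trace of a
#' spatio-temporal map, stacked as `K x T x I x C`.
#'
#' @param values numeric array `K x T x I x C`
#' @param spec the [band_spec()] used
#' @param fps sampling rate (Hz)
#' @return an object of class `multiband_stack`
#' @export
multiband_stack <- function(values, spec, fps) {
  assert_that(length(dim(values)) == 4, "values must be K x T x I x C")
  structure(list(values = values, band_spec = spec, fps = fps),
            class = "multiband_stack")
}

#' Decompose a spatio-temporal map into frequency bands
#'
#' For every region-channel trace: orthonormal DCT, in-place band masking for
#' each of the `K` bands, and inverse DCT back to the time domain. The result
#' is a `K x T x I x C` stack of band-limited signals; the operation is linear
#' in the input map.
#'
#' @param map a normalized [stmap()]
#' @param spec a [band_spec()]; its `fps` must match the map
#' @return a [multiband_stack()]
#' @export
decompose_multiband <- function(map, spec = band_spec(fps = map$fps)) {
  assert_that(inherits(map, "stmap"), "map must be an stmap")
  assert_that(inherits(spec, "band_spec"), "spec must be a band_spec")
  assert_that(isTRUE(all.equal(spec$fps, map$fps)),
              "band_spec fps (%g) does not match map fps (%g)",
              spec$fps, map$fps)
  v <- map$values
  d <- dim(v)
  out <- array(0, c(spec$K, d[1], d[2], d[3]))
  for (i in seq_len(d[2])) for (c in seq_len(d[3])) {
    co <- dct_ortho(v[, i, c])
    for (k in seq_len(spec$K)) {
      out[k, , i, c] <- idct_ortho(
        band_slice_zero_pad(co, spec$bands[k, ], spec$fps))
    }
  }
  multiband_stack(out, spec, map$fps)
}

# Flatten one band of a stack to the channels-x-time matrix the network eats:
# regions x color channels collapse to I*C feature channels.
band_to_channels <- function(stack, k) {
  v <- stack$values[k, , , , drop = TRUE]     # T x I x C
  d <- dim(v)
  t(matrix(v, nrow = d[1]))                   # (I*C) x T
}
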