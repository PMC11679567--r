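# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

assert_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stopf("%s contains non-finite values", what)
  invisible(TRUE)
}

#' Population standard deviation (ddof = 0)
#' @param x numeric vector
#' @return scalar
#' @keywords internal
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Derive a per-stream seed from a root seed and an index, staying < 2^31.
# Knuth multiplicative constant; double arithmetic is exact below 2^53.
derive_seed <- function(root, index) {
  as.integer((as.numeric(root) * 48271 + as.numeric(index) * 2654435761) %%
               2147483647)
}

#' Welch power spectral density estimate
#'
#' Hann-windowed, mean-detrended, 50%-overlapping segments averaged into a
#' one-sided PSD. Segments are zero-padded to `nfft` for a finer frequency
#' grid (interpolation of the spectrum, not added resolution).
#'
#' @param x numeric vector
#' @param fs sampling frequency (Hz)
#' @param nperseg samples per segment (default: whole signal)
#' @param nfft FFT length, >= nperseg
#' @return list with `freq` (Hz) and `power` vectors
#' @export
welch_psd <- function(x, fs, nperseg = length(x), nfft = max(nperseg, 4096L)) {
  n <- length(x)
  assert_that(n >= 8, "welch_psd needs at least 8 samples, got %d", n)
  nperseg <- min(nperseg, n)
  nfft <- max(nfft, nperseg)
  step <- max(1L, floor(nperseg / 2))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  acc <- numeric(nfft)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * win
    sp <- stats::fft(c(seg, numeric(nfft - nperseg)))
    acc <- acc + Mod(sp)^2
  }
  acc <- acc / (length(starts) * sum(win^2) * fs)
  half <- seq_len(floor(nfft / 2) + 1L)
  power <- acc[half]
  # one-sided: double everything except DC (and Nyquist when nfft even)
  dbl <- rep(2, length(half))
  dbl[1] <- 1
  if (nfft %% 2 == 0) dbl[length(half)] <- 1
  list(freq = (half - 1L) * fs / nfft, power = power * dbl)
}
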