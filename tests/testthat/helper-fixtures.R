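# Shared fixtures, built in code.

# small random region series
make_series <- function(nT = 64, nI = 2, fps = 30, seed = 1) {
  set.seed(seed)
  rgb_region_series(array(runif(nT * nI * 3, 0, 255), c(nT, nI, 3)),
                    fps = fps)
}

# normalized map carrying chosen per-trace signals (T x I x 3 from a list of
# trace-generating functions of time)
make_map_from_traces <- function(traces, fps = 30) {
  nT <- length(traces[[1]])
  nI <- length(traces)
  v <- array(0, c(nT, nI, 3))
  for (i in seq_len(nI)) for (c in 1:3) v[, i, c] <- traces[[i]]
  temporal_normalize(stmap(v, fps = fps))
}

# independent brute-force oracle for the band decomposition: explicit
# T x T orthonormal DCT-II matrix, row masking, explicit inverse
oracle_dct_matrix <- function(n) {
  M <- matrix(0, n, n)
  for (k in 0:(n - 1)) for (j in 0:(n - 1))
    M[k + 1, j + 1] <- cos(pi * k * (2 * j + 1) / (2 * n))
  M[1, ] <- M[1, ] * sqrt(1 / n)
  M[-1, ] <- M[-1, ] * sqrt(2 / n)
  M
}

oracle_band_filter <- function(x, band, fps) {
  n <- length(x)
  M <- oracle_dct_matrix(n)
  f <- (0:(n - 1)) * fps / (2 * n)
  keep <- f >= band[1] & f < band[2]
  Mk <- M
  Mk[!keep, ] <- 0
  as.numeric(t(M) %*% (Mk %*% x))
}

# pure tone phase-aligned to the DCT grid (half-sample offset), so it
# occupies exactly one DCT bin; f must sit on the bin grid fps/(2n)
dct_tone <- function(f, n, fps) {
  k0 <- f * 2 * n / fps
  cos(pi * k0 * (2 * (0:(n - 1)) + 1) / (2 * n))
}

# tiny network configuration used by gradient/shape tests
tiny_cfg <- function(seed = 7) {
  srrn_config(num_bands = 2, input_len = 64, input_channels = 3,
              tmsc_out = 2, encoder_depth = 2, ssa_segment = 8,
              seed = seed)
}
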