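# Signal refinement & reconstruction network (SRRN): one encoder/decoder
# branch per frequency band, independent parameters per branch, fused into a
# single BVP trace by a 1x1 convolution. The default configuration sits under
# hard budgets: <= 11,000 trainable parameters and <= 1.3e8 FLOPs for one
# forward pass on a 450-frame, 4-region input (1 MAC counted as 2 FLOPs).

#' SRRN configuration
#'
#' Channel widths and depths are free parameters; the parameter/FLOP budgets
#' are the normative constraints and are enforced at construction time.
#'
#' @param num_bands number of frequency-band branches (K)
#' @param input_len temporal length T of the input map (default 450 = 15 s at
#'   30 fps)
#' @param input_channels feature channels per band (default 12 = 4 regions x 3
#'   color channels)
#' @param tmsc_out output channels per kernel size in each temporal multiscale
#'   convolution (total channels = `3 * tmsc_out`)
#' @param kernel_sizes odd kernel sizes of the multiscale convolution
#' @param encoder_depth number of TMSC/BN/ELU/pool stages (each halves the
#'   temporal length, ceil mode)
#' @param deconv_kernel kernel size of the transposed convolutions
#' @param ssa_segment segment length (samples) of the spectrum self-attention
#' @param se_hidden hidden width of the squeeze-excitation channel gate
#' @param param_budget maximum trainable parameters (hard)
#' @param flop_budget maximum forward-pass FLOPs (hard)
#' @param seed integer seed for weight initialization
#' @return an object of class `srrn_config`
#' @export
srrn_config <- function(num_bands = 3L, input_len = 450L,
                        input_channels = 12L, tmsc_out = 3L,
                        kernel_sizes = c(3L, 5L, 7L), encoder_depth = 3L,
                        deconv_kernel = 5L, ssa_segment = 15L,
                        se_hidden = 4L, param_budget = 11000,
                        flop_budget = 1.3e8, seed = 1L) {
  assert_that(num_bands >= 1, "need at least one band branch")
  assert_that(all(kernel_sizes %% 2 == 1), "kernel sizes must be odd")
  assert_that(ssa_segment >= 8, "ssa_segment must be >= 8 samples")
  assert_that(encoder_depth >= 1, "encoder_depth must be >= 1")
  structure(list(num_bands = as.integer(num_bands),
                 input_len = as.integer(input_len),
                 input_channels = as.integer(input_channels),
                 tmsc_out = as.integer(tmsc_out),
                 kernel_sizes = as.integer(kernel_sizes),
                 encoder_depth = as.integer(encoder_depth),
                 deconv_kernel = as.integer(deconv_kernel),
                 ssa_segment = as.integer(ssa_segment),
                 se_hidden = as.integer(se_hidden),
                 param_budget = param_budget,
                 flop_budget = flop_budget,
                 seed = as.integer(seed)),
            class = "srrn_config")
}

# temporal lengths after each ceil-mode stride-2 pooling stage
encoder_lengths <- function(input_len, depth) {
  out <- integer(depth + 1)
  out[1] <- input_len
  for (j in seq_len(depth)) out[j + 1] <- as.integer(ceiling(out[j] / 2))
  out
}

build_branch <- function(cfg) {
  ch <- 3L * cfg$tmsc_out
  lens <- encoder_lengths(cfg$input_len, cfg$encoder_depth)
  enc <- list()
  in_ch <- cfg$input_channels
  for (j in seq_len(cfg$encoder_depth)) {
    enc <- c(enc, list(layer_tmsc(in_ch, cfg$tmsc_out, cfg$kernel_sizes),
                       layer_bn(ch), layer_elu(), layer_pool2()))
    in_ch <- ch
  }
  dec <- list()
  for (j in rev(seq_len(cfg$encoder_depth))) {
    dec <- c(dec, list(layer_deconv(ch, ch, cfg$deconv_kernel,
                                    target_len = lens[j]),
                       layer_bn(ch), layer_elu(),
                       layer_ssa(ch, cfg$ssa_segment, cfg$se_hidden)))
  }
  c(enc, dec)
}

#' Construct the SRRN
#'
#' Builds K independent branches plus the 1x1 fusion convolution, seeds all
#' weights from `cfg$seed`, and verifies the parameter/FLOP budgets; a
#' configuration that exceeds either budget fails construction.
#'
#' @param cfg an [srrn_config()]
#' @return an object of class `srrn` (list of branches + fusion layer)
#' @export
build_srrn <- function(cfg) {
  set.seed(cfg$seed)
  branches <- lapply(seq_len(cfg$num_bands), function(k) build_branch(cfg))
  ch <- 3L * cfg$tmsc_out
  fusion <- layer_conv1d(cfg$num_bands * ch, 1L, 1L)
  net <- structure(list(cfg = cfg, branches = branches, fusion = fusion),
                   class = "srrn")
  np <- count_params(net)
  nf <- count_flops(net)
  if (np > cfg$param_budget)
    stopf("configuration has %d trainable parameters, budget is %d",
          np, cfg$param_budget)
  if (nf > cfg$flop_budget)
    stopf("configuration needs %.3g FLOPs per forward pass, budget is %.3g",
          nf, cfg$flop_budget)
  net
}

#' Forward pass of the SRRN
#'
#' @param net an [build_srrn()] network
#' @param bands list of K arrays `(input_channels, T, B)` — one per frequency
#'   band, as produced by stacking [decompose_multiband()] outputs
#' @param training logical; use batch statistics (and keep caches for the
#'   backward pass) when `TRUE`
#' @return matrix `T x B` of recovered BVP traces
#' @export
srrn_forward <- function(net, bands, training = FALSE) {
  cfg <- net$cfg
  assert_that(length(bands) == cfg$num_bands,
              "expected %d band inputs, got %d", cfg$num_bands, length(bands))
  outs <- vector("list", cfg$num_bands)
  for (k in seq_len(cfg$num_bands)) {
    X <- bands[[k]]
    d <- dim(X)
    assert_that(d[1] == cfg$input_channels && d[2] == cfg$input_len,
                "band %d has shape %d x %d, expected %d x %d",
                k, d[1], d[2], cfg$input_channels, cfg$input_len)
    for (l in net$branches[[k]]) X <- layer_forward(l, X, training)
    outs[[k]] <- X
  }
  ch <- dim(outs[[1]])[1]
  B <- dim(outs[[1]])[3]
  Z <- array(0, c(cfg$num_bands * ch, cfg$input_len, B))
  for (k in seq_len(cfg$num_bands))
    Z[((k - 1) * ch + 1):(k * ch), , ] <- outs[[k]]
  Y <- layer_forward(net$fusion, Z, training)
  matrix(Y, nrow = cfg$input_len)
}

# Backward pass: dY is T x B gradient of the loss w.r.t. the fused output.
# Gradients accumulate into the layer environments (zero_grads() first).
srrn_backward <- function(net, dY) {
  cfg <- net$cfg
  B <- ncol(dY)
  dZ <- layer_backward(net$fusion, array(dY, c(1, cfg$input_len, B)))
  ch <- dim(dZ)[1] / cfg$num_bands
  for (k in seq_len(cfg$num_bands)) {
    dX <- dZ[((k - 1) * ch + 1):(k * ch), , , drop = FALSE]
    for (l in rev(net$branches[[k]])) dX <- layer_backward(l, dX)
  }
  invisible(NULL)
}

srrn_param_layers <- function(net) {
  collect_param_layers(c(net$branches, list(net$fusion)))
}

#' Count trainable parameters
#'
#' @param net an `srrn` network
#' @return integer number of trainable scalars
#' @export
count_params <- function(net) {
  sum(vapply(srrn_param_layers(net), layer_param_count, numeric(1)))
}

# analytic conv FLOPs at output length L: 1 MAC = 2 FLOPs, + one bias add
# per output element
conv_flops <- function(l, L) 2 * l$k * l$in_ch * l$out_ch * L + l$out_ch * L

ssa_flops <- function(l, L) {
  S <- ceiling(L / l$seg)
  Lp <- S * l$seg
  (2 * l$ch * Lp + Lp) +                           # 1x1 attention conv
    2 * l$seg * Lp +                               # per-segment DCT
    8 * l$seg * S + 4 * S +                        # cosine sims + softmax
    2 * (l$ch * l$hidden) * 2 + l$ch + l$hidden +  # SE gate
    l$ch * L +                                     # global average pool
    2 * l$ch * L                                   # two multiplicative gates
}

#' Count forward-pass FLOPs
#'
#' Analytic operation count for one forward pass at the configured input
#' shape, under the stated convention: one multiply-accumulate = 2 FLOPs;
#' batch-normalization, activations and pooling are counted once per output
#' element.
#'
#' @param net an `srrn` network
#' @param input_len temporal length of the input (default: configured T)
#' @return numeric FLOP count
#' @export
count_flops <- function(net, input_len = net$cfg$input_len) {
  cfg <- net$cfg
  total <- 0
  for (branch in net$branches) {
    L <- input_len
    ch <- cfg$input_channels
    for (l in branch) {
      if (l$type == "tmsc") {
        total <- total + sum(vapply(l$convs, conv_flops, numeric(1), L = L))
        ch <- l$out_ch
      } else if (l$type == "bn") {
        total <- total + l$ch * L
      } else if (l$type == "elu") {
        total <- total + ch * L
      } else if (l$type == "pool2") {
        L <- ceiling(L / 2)
        total <- total + ch * L
      } else if (l$type == "deconv") {
        L <- l$target_len
        ch <- l$out_ch
        total <- total + conv_flops(l$conv, L)
      } else if (l$type == "ssa") {
        total <- total + ssa_flops(l, L)
      }
    }
  }
  # fusion 1x1 conv at full length
  total + conv_flops(net$fusion, input_len)
}

#' Recover a BVP trace from a spatio-temporal map
#'
#' Runs decomposition and the network in inference mode on one normalized
#' map.
#'
#' @param net a trained `srrn`
#' @param map a normalized [stmap()]
#' @param spec the [band_spec()] matching the network's band branches
#' @return a `bvp_signal` object (values + fps)
#' @export
predict_bvp <- function(net, map, spec = band_spec(fps = map$fps)) {
  stack <- decompose_multiband(map, spec)
  bands <- lapply(seq_len(net$cfg$num_bands), function(k) {
    m <- band_to_channels(stack, k)
    array(m, c(dim(m), 1L))
  })
  y <- srrn_forward(net, bands, training = FALSE)
  bvp_signal(as.numeric(y), fps = map$fps)
}

#' BVP signal container
#' @param values numeric vector, the recovered pulse waveform
#' @param fps sampling rate (Hz)
#' @return object of class `bvp_signal`
#' @export
bvp_signal <- function(values, fps) {
  assert_finite(values, "BVP signal")
  structure(list(values = as.numeric(values), fps = fps),
            class = "bvp_signal")
}

# ---- checkpointing ---------------------------------------------------------

#' Extract all weights (and BN running statistics) as a plain list
#' @param net an `srrn`
#' @return named list of numeric arrays
#' @export
srrn_state <- function(net) {
  layers <- srrn_param_layers(net)
  st <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (p in l$params) st[[sprintf("L%03d.%s", i, p)]] <- get(p, envir = l)
    if (l$type == "bn") {
      st[[sprintf("L%03d.run_mean", i)]] <- l$run_mean
      st[[sprintf("L%03d.run_var", i)]] <- l$run_var
    }
  }
  st
}

#' Load weights produced by [srrn_state()] into a network of the same
#' configuration
#' @param net an `srrn`
#' @param state list from [srrn_state()]
#' @return the network, weights replaced
#' @export
srrn_load_state <- function(net, state) {
  layers <- srrn_param_layers(net)
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (p in l$params) {
      key <- sprintf("L%03d.%s", i, p)
      assert_that(key %in% names(state), "checkpoint is missing '%s'", key)
      cur <- get(p, envir = l)
      val <- state[[key]]
      assert_that(length(val) == length(cur),
                  "checkpoint entry '%s' has wrong size", key)
      if (is.matrix(cur)) val <- matrix(val, nrow(cur), ncol(cur))
      assign(p, val, envir = l)
    }
    if (l$type == "bn") {
      l$run_mean <- as.numeric(state[[sprintf("L%03d.run_mean", i)]])
      l$run_var <- as.numeric(state[[sprintf("L%03d.run_var", i)]])
    }
  }
  net
}

#' Save a network checkpoint (config + weights) to an RDS file
#' @param net an `srrn`
#' @param path file path
#' @export
save_srrn <- function(net, path) {
  saveRDS(list(config = unclass(net$cfg), state = srrn_state(net)), path)
}

#' Load a network checkpoint written by [save_srrn()]
#' @param path file path
#' @return an `srrn` with restored weights
#' @export
load_srrn <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(srrn_config, ck$config)
  srrn_load_state(build_srrn(cfg), ck$state)
}
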