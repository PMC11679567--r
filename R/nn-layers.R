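# Minimal 1-D neural-network layer library with explicit forward/backward
# passes on BLAS matrix ops. Feature tensors are arrays of dim (C, L, B):
# channels x time x batch. Layers are environments so gradients and caches
# mutate in place; all convolutions are stride-1 same-padding, downsampling
# is done by pooling and upsampling by zero-stuffed ("transposed") conv.

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e$params <- character(0)
  class(e) <- c(paste0("pb_", type), "pb_layer")
  e
}

glorot <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  stats::runif(n, -lim, lim)
}

# ---- im2col / col2im (same padding) ----------------------------------------

im2col <- function(X, k) {
  d <- dim(X)
  im2col_cpp(X, d[1], d[2], d[3], as.integer(k))
}

col2im <- function(Dcol, C, k, L, B) {
  col2im_cpp(Dcol, as.integer(C), as.integer(L), as.integer(B),
             as.integer(k))
}

# ---- layers ----------------------------------------------------------------

layer_conv1d <- function(in_ch, out_ch, k) {
  stopifnot(k %% 2 == 1)
  l <- new_layer("conv1d", in_ch = in_ch, out_ch = out_ch, k = k)
  l$W <- matrix(glorot(in_ch * k, out_ch, out_ch * in_ch * k),
                nrow = out_ch)
  l$b <- numeric(out_ch)
  l$params <- c("W", "b")
  l
}

conv1d_forward <- function(l, X) {
  d <- dim(X)
  if (d[2] < l$k) stopf("conv1d: input length %d < kernel size %d", d[2], l$k)
  Xcol <- im2col(X, l$k)
  Y <- l$W %*% Xcol + l$b
  l$cache <- list(Xcol = Xcol, d = d)
  array(Y, c(l$out_ch, d[2], d[3]))
}

conv1d_backward <- function(l, dY) {
  d <- l$cache$d
  dYm <- dY
  dim(dYm) <- c(l$out_ch, d[2] * d[3])
  l$gW <- l$gW + tcrossprod(dYm, l$cache$Xcol)
  l$gb <- l$gb + rowSums(dYm)
  dXcol <- crossprod(l$W, dYm)
  col2im(dXcol, d[1], l$k, d[2], d[3])
}

# Temporal multiscale convolution: parallel convolutions with odd kernel
# sizes (default 3/5/7), outputs concatenated along the channel axis.
layer_tmsc <- function(in_ch, out_per_kernel, kernel_sizes = c(3L, 5L, 7L)) {
  stopifnot(all(kernel_sizes %% 2 == 1))
  l <- new_layer("tmsc", in_ch = in_ch, out_per_kernel = out_per_kernel,
                 kernel_sizes = as.integer(kernel_sizes))
  l$convs <- lapply(kernel_sizes, function(k)
    layer_conv1d(in_ch, out_per_kernel, k))
  l$out_ch <- out_per_kernel * length(kernel_sizes)
  l
}

tmsc_forward <- function(l, X) {
  outs <- lapply(l$convs, function(cv) conv1d_forward(cv, X))
  d <- dim(outs[[1]])
  Y <- array(0, c(l$out_ch, d[2], d[3]))
  o <- 0L
  for (y in outs) {
    Y[(o + 1L):(o + l$out_per_kernel), , ] <- y
    o <- o + l$out_per_kernel
  }
  Y
}

tmsc_backward <- function(l, dY) {
  o <- 0L
  dX <- NULL
  for (cv in l$convs) {
    dyi <- dY[(o + 1L):(o + l$out_per_kernel), , , drop = FALSE]
    dxi <- conv1d_backward(cv, dyi)
    dX <- if (is.null(dX)) dxi else dX + dxi
    o <- o + l$out_per_kernel
  }
  dX
}

layer_bn <- function(ch, momentum = 0.1, eps = 1e-5) {
  l <- new_layer("bn", ch = ch, momentum = momentum, eps = eps)
  l$gamma <- rep(1, ch)
  l$beta <- numeric(ch)
  l$run_mean <- numeric(ch)
  l$run_var <- rep(1, ch)
  l$params <- c("gamma", "beta")
  l
}

bn_forward <- function(l, X, training) {
  d <- dim(X)
  Xm <- X
  dim(Xm) <- c(d[1], d[2] * d[3])     # C x (L*B)
  if (training) {
    mu <- rowMeans(Xm)
    xc <- Xm - mu
    va <- rowMeans(xc^2)
    l$run_mean <- (1 - l$momentum) * l$run_mean + l$momentum * mu
    l$run_var <- (1 - l$momentum) * l$run_var + l$momentum * va
  } else {
    mu <- l$run_mean
    xc <- Xm - mu
    va <- l$run_var
  }
  istd <- 1 / sqrt(va + l$eps)
  xhat <- xc * istd
  Y <- xhat * l$gamma + l$beta
  l$cache <- list(xhat = xhat, istd = istd, d = d, training = training)
  array(Y, d)
}

bn_backward <- function(l, dY) {
  cc <- l$cache
  d <- cc$d
  n <- prod(d[2:3])
  dYm <- dY
  dim(dYm) <- c(d[1], n)
  l$ggamma <- l$ggamma + rowSums(dYm * cc$xhat)
  l$gbeta <- l$gbeta + rowSums(dYm)
  dxhat <- dYm * l$gamma
  if (cc$training) {
    dXm <- cc$istd * (dxhat - rowMeans(dxhat) -
                        cc$xhat * rowMeans(dxhat * cc$xhat))
  } else {
    dXm <- dxhat * cc$istd
  }
  array(dXm, d)
}

layer_elu <- function(alpha = 1) new_layer("elu", alpha = alpha)

elu_forward <- function(l, X) {
  neg <- X < 0
  Y <- X
  Y[neg] <- l$alpha * (exp(X[neg]) - 1)
  l$cache <- list(Y = Y, neg = neg)
  Y
}

elu_backward <- function(l, dY) {
  cc <- l$cache
  dX <- dY
  dX[cc$neg] <- dY[cc$neg] * (cc$Y[cc$neg] + l$alpha)
  dX
}

# Average pooling, width/stride 2, ceil mode (a trailing odd sample forms its
# own window), so a length-L map pools to ceiling(L / 2).
layer_pool2 <- function() new_layer("pool2")

pool2_forward <- function(l, X) {
  d <- dim(X)
  L <- d[2]
  Lh <- L %/% 2L
  Lout <- as.integer(ceiling(L / 2))
  Y <- array(0, c(d[1], Lout, d[3]))
  if (Lh > 0) {
    ev <- 2L * seq_len(Lh)
    Y[, seq_len(Lh), ] <- (X[, ev - 1L, , drop = FALSE] +
                             X[, ev, , drop = FALSE]) / 2
  }
  if (L %% 2 == 1) Y[, Lout, ] <- X[, L, ]
  l$cache <- list(d = d, Lout = Lout)
  Y
}

pool2_backward <- function(l, dY) {
  d <- l$cache$d
  L <- d[2]
  Lh <- L %/% 2L
  dX <- array(0, d)
  if (Lh > 0) {
    ev <- 2L * seq_len(Lh)
    half <- dY[, seq_len(Lh), , drop = FALSE] / 2
    dX[, ev - 1L, ] <- half
    dX[, ev, ] <- half
  }
  if (L %% 2 == 1) dX[, L, ] <- dY[, l$cache$Lout, ]
  dX
}

# Transposed convolution, stride 2: the input is zero-stuffed onto the even
# grid of the target length, then convolved (stride-1, same padding). The
# target length must be 2L-1 or 2L for an input of length L.
layer_deconv <- function(in_ch, out_ch, k, target_len) {
  l <- new_layer("deconv", in_ch = in_ch, out_ch = out_ch, k = k,
                 target_len = as.integer(target_len))
  l$conv <- layer_conv1d(in_ch, out_ch, k)
  l
}

deconv_forward <- function(l, X) {
  d <- dim(X)
  L <- d[2]
  Lt <- l$target_len
  if (Lt < 2L * L - 1L || Lt > 2L * L)
    stopf("deconv: target length %d incompatible with input length %d", Lt, L)
  U <- array(0, c(d[1], Lt, d[3]))
  pos <- 2L * seq_len(L) - 1L
  U[, pos, ] <- X
  l$cache_pos <- pos
  conv1d_forward(l$conv, U)
}

deconv_backward <- function(l, dY) {
  dU <- conv1d_backward(l$conv, dY)
  dU[, l$cache_pos, , drop = FALSE]
}

# ---- spectrum self-attention ------------------------------------------------

# Orthonormal DCT-II matrix (small, for per-segment spectral descriptors).
dct_matrix <- function(n) {
  M <- cos(pi * outer(0:(n - 1), 2 * (0:(n - 1)) + 1) / (2 * n))
  M[1, ] <- M[1, ] * sqrt(1 / n)
  M[-1, ] <- M[-1, ] * sqrt(2 / n)
  M
}

# Spectrum self-attention: a learned 1x1 convolution collapses the feature
# channels to one attention trace; the trace is segmented in time, each
# segment is DCT-transformed into a spectral descriptor, and segments whose
# descriptors deviate from the mean descriptor (cosine similarity + softmax)
# are down-weighted. A squeeze-excitation channel gate then aggregates the
# re-weighted signal. Output has the input's shape.
layer_ssa <- function(ch, segment_len, se_hidden = 4L) {
  stopifnot(segment_len >= 8)
  l <- new_layer("ssa", ch = ch, seg = as.integer(segment_len),
                 hidden = as.integer(se_hidden), eps = 1e-8)
  l$w_attn <- matrix(glorot(ch, 1, ch), nrow = 1)
  l$b_attn <- 0
  l$W1 <- matrix(glorot(ch, se_hidden, se_hidden * ch), nrow = se_hidden)
  l$b1 <- numeric(se_hidden)
  l$W2 <- matrix(glorot(se_hidden, ch, ch * se_hidden), nrow = ch)
  l$b2 <- numeric(ch)
  l$D <- dct_matrix(l$seg)
  l$params <- c("w_attn", "b_attn", "W1", "b1", "W2", "b2")
  l
}

# Segment attention weights for one batch column. Descriptors are
# normalized to unit length before averaging so the consensus direction is
# set by the majority of segments, not by a single high-power outlier; each
# segment is then scored by its cosine to that consensus and the scores are
# softmax-normalized.
ssa_weights <- function(l, a_pad, S) {
  A <- matrix(a_pad, nrow = l$seg)            # seg x S
  Dsc <- l$D %*% A                            # descriptors
  nd <- sqrt(colSums(Dsc^2))
  U <- sweep(Dsc, 2, pmax(nd, l$eps), `/`)    # unit descriptors
  m <- rowMeans(U)                            # consensus direction
  nm <- sqrt(sum(m^2))
  cs <- as.numeric(crossprod(U, m)) / (nm + l$eps)
  e <- exp(cs - max(cs))
  w <- e / sum(e)
  list(A = A, Dsc = Dsc, U = U, m = m, nd = nd, nm = nm, cs = cs, w = w)
}

ssa_forward <- function(l, X, training) {
  d <- dim(X)
  C <- d[1]; L <- d[2]; B <- d[3]
  S <- as.integer(ceiling(L / l$seg))
  Lp <- S * l$seg
  # attention trace via 1x1 conv
  Xm <- matrix(X, nrow = C)
  a <- as.numeric(l$w_attn %*% Xm) + l$b_attn    # length L*B
  a_arr <- array(0, c(Lp, B))
  a_arr[seq_len(L), ] <- matrix(a, nrow = L)
  per_b <- lapply(seq_len(B), function(b) ssa_weights(l, a_arr[, b], S))
  W <- vapply(per_b, `[[`, numeric(S), "w")     # S x B
  W <- matrix(W, nrow = S)
  # broadcast: per-sample weight, scaled by S so a uniform signal is unchanged
  useg <- S * W                                  # S x B
  u_full <- useg[rep(seq_len(S), each = l$seg), , drop = FALSE][seq_len(L), ,
                                                                drop = FALSE]
  # squeeze-excitation channel gate (global average pool via rowsum)
  Xm2 <- X; dim(Xm2) <- c(C * L, B)
  p <- rowsum(Xm2, rep(seq_len(C), times = L)) / L   # C x B
  h <- l$W1 %*% p + l$b1
  hr <- pmax(h, 0)
  z <- l$W2 %*% hr + l$b2
  g <- 1 / (1 + exp(-z))                         # C x B
  u_b <- array(rep(u_full, each = C), c(C, L, B))
  g_b <- array(rep(g, times = L), c(C, B, L))
  g_b <- aperm(g_b, c(1, 3, 2))
  Y <- X * u_b * g_b
  l$cache <- list(d = d, S = S, Lp = Lp, per_b = per_b, W = W,
                  u_b = u_b, g_b = g_b, g = g, hr = hr, h = h, p = p, X = X)
  Y
}

# backward through cosine-to-consensus + softmax for one column
ssa_weights_backward <- function(l, pb, dw, S) {
  w <- pb$w
  dcs <- w * (dw - sum(dw * w))               # softmax backward
  U <- pb$U; m <- pb$m; nd <- pb$nd; nm <- pb$nm; cs <- pb$cs
  ndg <- pmax(nd, l$eps)
  nmg <- nm + l$eps
  # c_s = (u_s . m) / (|m| + eps), u_s = d_s / |d_s|
  # direct term (consensus m held fixed):
  # dc_s/dd_s = (m - u_s (u_s . m)) / (|d_s| (|m| + eps))
  um <- as.numeric(crossprod(U, m))
  dD <- sweep(outer(m, dcs / nmg) -
                sweep(U, 2, um * dcs / nmg, `*`), 2, ndg, `/`)
  # term through m = rowMeans(U):
  # dc_s'/dm = u_s'/(|m|+eps) - c_s' m / (|m| (|m|+eps))
  dm <- U %*% (dcs / nmg) - m * sum(dcs * cs) / (pmax(nm, l$eps) * nmg)
  # dm/dd_s = (I - u_s u_s^T) / (S |d_s|)
  udm <- as.numeric(crossprod(U, dm))
  dD <- dD + sweep(matrix(dm, l$seg, S) - sweep(U, 2, udm, `*`),
                   2, S * ndg, `/`)
  dA <- crossprod(l$D, dD)
  as.numeric(dA)
}

ssa_backward <- function(l, dY) {
  cc <- l$cache
  d <- cc$d; C <- d[1]; L <- d[2]; B <- d[3]
  S <- cc$S
  X <- cc$X
  dX <- dY * cc$u_b * cc$g_b
  # gradient into the per-sample weight path
  Zu <- dY * X * cc$g_b
  dim(Zu) <- c(C * L, B)
  du_full <- rowsum(Zu, rep(seq_len(L), each = C))     # L x B
  du_pad <- matrix(0, cc$Lp, B)
  du_pad[seq_len(L), ] <- du_full
  dW <- S * rowsum(du_pad, rep(seq_len(S), each = l$seg))  # S x B
  da_pad <- matrix(0, cc$Lp, B)
  for (b in seq_len(B))
    da_pad[, b] <- ssa_weights_backward(l, cc$per_b[[b]], dW[, b], S)
  da <- da_pad[seq_len(L), , drop = FALSE]             # L x B
  da_row <- matrix(as.numeric(da), nrow = 1)           # 1 x (L*B)
  Xm <- matrix(X, nrow = C)
  l$gw_attn <- l$gw_attn + da_row %*% t(Xm)
  l$gb_attn <- l$gb_attn + sum(da_row)
  dX <- dX + array(crossprod(l$w_attn, da_row), d)
  # gradient into the channel gate
  Zg <- dY * X * cc$u_b
  dim(Zg) <- c(C * L, B)
  dg <- rowsum(Zg, rep(seq_len(C), times = L))         # C x B
  dz <- dg * cc$g * (1 - cc$g)
  l$gW2 <- l$gW2 + dz %*% t(cc$hr)
  l$gb2 <- l$gb2 + rowSums(dz)
  dhr <- crossprod(l$W2, dz)
  dh <- dhr * (cc$h > 0)
  l$gW1 <- l$gW1 + dh %*% t(cc$p)
  l$gb1 <- l$gb1 + rowSums(dh)
  dp <- crossprod(l$W1, dh)                            # C x B
  dX <- dX + aperm(array(rep(dp / L, times = L), c(C, B, L)), c(1, 3, 2))
  dX
}

# ---- generic dispatch -------------------------------------------------------

layer_forward <- function(l, X, training = FALSE) {
  switch(l$type,
         conv1d = conv1d_forward(l, X),
         tmsc   = tmsc_forward(l, X),
         bn     = bn_forward(l, X, training),
         elu    = elu_forward(l, X),
         pool2  = pool2_forward(l, X),
         deconv = deconv_forward(l, X),
         ssa    = ssa_forward(l, X, training),
         stopf("unknown layer type '%s'", l$type))
}

layer_backward <- function(l, dY) {
  switch(l$type,
         conv1d = conv1d_backward(l, dY),
         tmsc   = tmsc_backward(l, dY),
         bn     = bn_backward(l, dY),
         elu    = elu_backward(l, dY),
         pool2  = pool2_backward(l, dY),
         deconv = deconv_backward(l, dY),
         ssa    = ssa_backward(l, dY),
         stopf("unknown layer type '%s'", l$type))
}

# recursively collect parameter-bearing layers
collect_param_layers <- function(l) {
  if (is.environment(l)) {
    sub <- list()
    if (!is.null(l$convs)) sub <- l$convs
    if (!is.null(l$conv)) sub <- c(sub, list(l$conv))
    c(if (length(l$params) > 0) list(l) else list(),
      unlist(lapply(sub, collect_param_layers), recursive = FALSE))
  } else {
    unlist(lapply(l, collect_param_layers), recursive = FALSE)
  }
}

zero_grads <- function(layers) {
  for (l in layers) for (p in l$params)
    assign(paste0("g", p), get(p, envir = l) * 0, envir = l)
  invisible(NULL)
}

layer_param_count <- function(l) {
  sum(vapply(l$params, function(p) length(get(p, envir = l)), numeric(1)))
}
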