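# Training: negative-Pearson loss, HR-stratified over-sampling batches, and
# the two-phase schedule (all samples at a large learning rate, then
# HR-balanced batches at a small one).

#' Negative-Pearson loss
#'
#' `1 - r(pred, target)` with `r` the sample Pearson correlation, so perfect
#' waveform agreement scores 0 and a sign-flipped waveform scores 2. The loss
#' is invariant to positive affine rescaling of either argument, which makes
#' it the natural criterion for pulse waveforms whose absolute amplitude is
#' arbitrary. A constant prediction has undefined correlation; it is treated
#' as r = 0 (loss 1) with a warning.
#'
#' @param pred,target numeric vectors of equal length >= 2; target must be
#'   non-constant
#' @return scalar in `[0, 2]`
#' @export
pearson_loss <- function(pred, target) {
  n <- length(pred)
  assert_that(n == length(target), "pred and target lengths differ")
  assert_that(n >= 2, "need at least 2 samples")
  st <- pop_sd(target)
  assert_that(st > 0, "target waveform is constant")
  sp <- pop_sd(pred)
  if (sp == 0) {
    warning("constant prediction: Pearson r undefined, treated as 0")
    return(1)
  }
  r <- mean((pred - mean(pred)) * (target - mean(target))) / (sp * st)
  1 - r
}

# gradient of pearson_loss w.r.t. pred (vector); target non-constant,
# non-constant pred assumed (training never starts at an exact constant)
pearson_loss_grad <- function(pred, target) {
  n <- length(pred)
  pc <- pred - mean(pred)
  tc <- target - mean(target)
  sp <- sqrt(mean(pc^2))
  st <- sqrt(mean(tc^2))
  if (sp == 0) return(numeric(n))
  r <- mean(pc * tc) / (sp * st)
  -(tc / (n * sp * st) - r * pc / (n * sp^2))
}

#' Heart-rate grouping for stratified sampling
#'
#' Partitions the HR axis into bins; every sample is assigned to exactly one
#' group by its ground-truth HR (values outside the edges clamp to the first/
#' last bin).
#'
#' @param bin_edges increasing numeric vector of bin boundaries in bpm
#'   (default: 10-bpm bins over 40-180 bpm)
#' @return an object of class `hr_grouping` with a `group_of(hr)` function
#' @export
hr_grouping <- function(bin_edges = seq(40, 180, by = 10)) {
  assert_that(length(bin_edges) >= 2 && all(diff(bin_edges) > 0),
              "bin_edges must be increasing with at least 2 values")
  n_bins <- length(bin_edges) - 1L
  group_of <- function(hr) {
    g <- findInterval(hr, bin_edges, rightmost.closed = TRUE)
    pmin(pmax(g, 1L), n_bins)
  }
  structure(list(bin_edges = bin_edges, n_bins = n_bins,
                 group_of = group_of),
            class = "hr_grouping")
}

#' HR-stratified over-sampling batches
#'
#' Builds `n_batches` batches in which every occupied HR group contributes the
#' same number of samples: `floor(batch_size / G)` each, with the remainder
#' assigned round-robin. Groups with fewer samples than their quota are
#' sampled with replacement (over-sampling). Deterministic under `seed`.
#'
#' @param hrs numeric vector of ground-truth HRs (one per training record)
#' @param grouping an [hr_grouping()]
#' @param batch_size samples per batch; must be >= the number of occupied
#'   groups
#' @param n_batches number of batches to draw
#' @param seed integer seed
#' @return list of integer index vectors into `hrs`
#' @export
stratified_batches <- function(hrs, grouping, batch_size, n_batches,
                               seed = 1L) {
  g <- grouping$group_of(hrs)
  occupied <- sort(unique(g))
  G <- length(occupied)
  assert_that(G >= 1, "no occupied HR groups")
  assert_that(batch_size >= G,
              "batch_size (%d) must be >= number of occupied groups (%d)",
              batch_size, G)
  members <- lapply(occupied, function(gr) which(g == gr))
  base <- batch_size %/% G
  extra <- batch_size %% G
  set.seed(seed)
  batches <- vector("list", n_batches)
  for (b in seq_len(n_batches)) {
    # remainder rotates round-robin across batches
    quota <- rep(base, G)
    if (extra > 0) {
      who <- ((b - 1L + seq_len(extra) - 1L) %% G) + 1L
      quota[who] <- quota[who] + 1L
    }
    idx <- integer(0)
    for (j in seq_len(G)) {
      pool <- members[[j]]
      take <- quota[j]
      idx <- c(idx, if (take <= length(pool))
        pool[sample.int(length(pool), take)]
        else sample(pool, take, replace = TRUE))
    }
    batches[[b]] <- sample(idx)   # shuffle within the batch
  }
  batches
}

#' Training plan
#'
#' @param phase1_lr,phase2_lr learning rates of the two phases; phase 1 (all
#'   samples, plain shuffling) must use the larger rate
#' @param phase1_epochs,phase2_epochs epochs per phase
#' @param batch_size samples per batch
#' @param rng_seed seed governing shuffling, stratified sampling and noise
#' @param adam_beta1,adam_beta2,adam_eps Adam optimizer settings
#' @return an object of class `train_plan`
#' @export
train_plan <- function(phase1_lr = 1e-3, phase2_lr = 1e-4,
                       phase1_epochs = 10L, phase2_epochs = 5L,
                       batch_size = 32L, rng_seed = 1L,
                       adam_beta1 = 0.9, adam_beta2 = 0.999,
                       adam_eps = 1e-8) {
  assert_that(phase1_lr > phase2_lr && phase2_lr > 0,
              "need phase1_lr > phase2_lr > 0")
  structure(list(phase1_lr = phase1_lr, phase2_lr = phase2_lr,
                 phase1_epochs = as.integer(phase1_epochs),
                 phase2_epochs = as.integer(phase2_epochs),
                 batch_size = as.integer(batch_size),
                 rng_seed = as.integer(rng_seed),
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps),
            class = "train_plan")
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(l) {
    st <- list()
    for (p in l$params) {
      v <- get(p, envir = l)
      st[[p]] <- list(m = v * 0, v = v * 0)
    }
    st
  })
}

adam_step <- function(layers, state, lr, t, beta1, beta2, eps) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (p in l$params) {
      g <- get(paste0("g", p), envir = l)
      s <- state[[i]][[p]]
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g^2
      mhat <- s$m / (1 - beta1^t)
      vhat <- s$v / (1 - beta2^t)
      assign(p, get(p, envir = l) - lr * mhat / (sqrt(vhat) + eps), envir = l)
      state[[i]][[p]] <- s
    }
  }
  state
}

# ---- sample records and batching -------------------------------------------

#' Bundle a normalized spatio-temporal map with its training targets
#'
#' @param stmap a normalized [stmap()]
#' @param gt_bvp numeric vector, ground-truth BVP resampled to the map's
#'   frame grid
#' @param gt_hr ground-truth heart rate (bpm), within 36-240
#' @return an object of class `sample_record`
#' @export
sample_record <- function(stmap, gt_bvp, gt_hr) {
  assert_that(inherits(stmap, "stmap"), "stmap must be an stmap")
  assert_that(length(gt_bvp) == dim(stmap$values)[1],
              "gt_bvp length must match the map's temporal length")
  assert_finite(gt_bvp, "ground-truth BVP")
  assert_that(gt_hr >= 36 && gt_hr <= 240,
              "gt_hr %.1f bpm outside the physiological range [36, 240]",
              gt_hr)
  structure(list(stmap = stmap, gt_bvp = as.numeric(gt_bvp), gt_hr = gt_hr),
            class = "sample_record")
}

# decompose all records once and keep per-band channel matrices
precompute_bands <- function(records, spec) {
  lapply(records, function(rec) {
    stack <- decompose_multiband(rec$stmap, spec)
    lapply(seq_len(spec$K), function(k) band_to_channels(stack, k))
  })
}

# assemble list-of-K (C x T x B) arrays for the given record indices
gather_batch <- function(band_cache, idx, K) {
  d <- dim(band_cache[[1]][[1]])
  lapply(seq_len(K), function(k) {
    arr <- array(0, c(d[1], d[2], length(idx)))
    for (j in seq_along(idx)) arr[, , j] <- band_cache[[idx[j]]][[k]]
    arr
  })
}

run_epoch <- function(net, band_cache, targets, batches, layers, adam,
                      lr, step0, plan) {
  K <- net$cfg$num_bands
  total <- 0
  t <- step0
  for (idx in batches) {
    bands <- gather_batch(band_cache, idx, K)
    y <- srrn_forward(net, bands, training = TRUE)
    dY <- matrix(0, nrow(y), ncol(y))
    loss_b <- 0
    for (j in seq_along(idx)) {
      tgt <- targets[[idx[j]]]
      loss_b <- loss_b + pearson_loss(y[, j], tgt)
      dY[, j] <- pearson_loss_grad(y[, j], tgt) / length(idx)
    }
    loss_b <- loss_b / length(idx)
    if (!is.finite(loss_b))
      stopf("training diverged: non-finite loss at step %d", t + 1)
    zero_grads(layers)
    srrn_backward(net, dY)
    t <- t + 1
    adam <- adam_step(layers, adam, lr, t, plan$adam_beta1,
                      plan$adam_beta2, plan$adam_eps)
    total <- total + loss_b
  }
  list(loss = total / max(1, length(batches)), steps = t, adam = adam)
}

#' Train the SRRN with the two-phase over-sampling schedule
#'
#' Phase 1 passes over all records in shuffled order at `phase1_lr`; phase 2
#' continues at the smaller `phase2_lr` with HR-stratified over-sampling
#' batches, so every heart-rate group receives equal exposure regardless of
#' how imbalanced the training distribution is. The loss is the negative
#' Pearson correlation between predicted and ground-truth BVP. Fully
#' deterministic under `plan$rng_seed`.
#'
#' @param net an `srrn` from [build_srrn()]
#' @param records list of [sample_record()]s
#' @param plan a [train_plan()]
#' @param grouping an [hr_grouping()] (phase 2 stratification)
#' @param spec the [band_spec()] used to decompose each record
#' @param use_oversampling set `FALSE` to run phase 2 with plain shuffled
#'   batches instead (ablation switch)
#' @param verbose print per-epoch losses?
#' @return list with the trained `net` and a `history` data.frame
#'   (epoch, phase, loss)
#' @export
train_srrn <- function(net, records, plan = train_plan(),
                       grouping = hr_grouping(),
                       spec = band_spec(fps = records[[1]]$stmap$fps),
                       use_oversampling = TRUE, verbose = FALSE) {
  assert_that(length(records) >= 2, "need at least 2 training records")
  n <- length(records)
  band_cache <- precompute_bands(records, spec)
  targets <- lapply(records, `[[`, "gt_bvp")
  hrs <- vapply(records, `[[`, numeric(1), "gt_hr")
  layers <- srrn_param_layers(net)
  adam <- adam_init(layers)
  history <- list()
  step <- 0L
  set.seed(plan$rng_seed)
  for (ep in seq_len(plan$phase1_epochs)) {
    ord <- sample(n)
    batches <- split(ord, ceiling(seq_along(ord) / plan$batch_size))
    res <- run_epoch(net, band_cache, targets, batches, layers, adam,
                     plan$phase1_lr, step, plan)
    adam <- res$adam; step <- res$steps
    history[[length(history) + 1]] <-
      data.frame(epoch = ep, phase = 1L, loss = res$loss)
    if (verbose) message(sprintf("phase 1 epoch %d: loss %.4f", ep, res$loss))
  }
  n_batches <- max(1L, floor(n / plan$batch_size))
  for (ep in seq_len(plan$phase2_epochs)) {
    if (use_oversampling) {
      batches <- stratified_batches(hrs, grouping, plan$batch_size,
                                    n_batches,
                                    seed = derive_seed(plan$rng_seed, ep))
    } else {
      set.seed(derive_seed(plan$rng_seed, ep))
      ord <- sample(n)
      batches <- split(ord, ceiling(seq_along(ord) / plan$batch_size))
    }
    res <- run_epoch(net, band_cache, targets, batches, layers, adam,
                     plan$phase2_lr, step, plan)
    adam <- res$adam; step <- res$steps
    history[[length(history) + 1]] <-
      data.frame(epoch = plan$phase1_epochs + ep, phase = 2L,
                 loss = res$loss)
    if (verbose) message(sprintf("phase 2 epoch %d: loss %.4f", ep, res$loss))
  }
  list(net = net, history = do.call(rbind, history))
}
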