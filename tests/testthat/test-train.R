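# Loss, stratified over-sampling batches, two-phase training mechanics.

test_that("negative-Pearson loss hits its closed forms", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_loss(x, x), 0, tolerance = 1e-12)
  expect_equal(pearson_loss(-x, x), 2, tolerance = 1e-12)
  expect_equal(pearson_loss(c(1, 2, 3, 4), c(1, 2, 3, 5)),
               1 - 0.9827, tolerance = 1e-3)
  expect_warning(l <- pearson_loss(rep(1, 4), x), "constant")
  expect_equal(l, 1)
  expect_error(pearson_loss(x, rep(2, 4)), "constant")
})

test_that("pearson loss is invariant to positive affine maps of both sides", {
  set.seed(31)
  for (i in 1:20) {
    p <- rnorm(50); t <- rnorm(50)
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    cc <- runif(1, 0.1, 5); dd <- rnorm(1)
    expect_lt(abs(pearson_loss(a * p + b, cc * t + dd) -
                    pearson_loss(p, t)), 1e-9)
  }
})

test_that("pearson loss gradient matches finite differences", {
  set.seed(32)
  p <- rnorm(30); t <- rnorm(30)
  g <- pulseband:::pearson_loss_grad(p, t)
  eps <- 1e-7
  for (j in sample(30, 5)) {
    p1 <- p; p1[j] <- p[j] + eps
    p2 <- p; p2[j] <- p[j] - eps
    num <- (pearson_loss(p1, t) - pearson_loss(p2, t)) / (2 * eps)
    expect_lt(abs(num - g[j]), 1e-5)
  }
})

test_that("hr grouping assigns each sample to exactly one bin", {
  g <- hr_grouping()
  expect_equal(g$n_bins, 14)
  expect_equal(g$group_of(c(45, 75, 175)), c(1L, 4L, 14L))
  # out-of-range values clamp instead of dropping
  expect_equal(g$group_of(c(36, 240)), c(1L, 14L))
})

test_that("stratified batches balance groups and over-sample small ones", {
  g <- hr_grouping(c(60, 80, 100, 120, 140))
  # G = 4 occupied groups, batch 16 -> exactly 4 per group per batch
  hrs <- c(runif(100, 60, 79), runif(5, 80, 99), runif(5, 100, 119),
           runif(5, 120, 139))
  batches <- stratified_batches(hrs, g, batch_size = 16, n_batches = 100,
                                seed = 5)
  grp <- g$group_of(hrs)
  counts <- matrix(0, 100, 4)
  for (b in seq_along(batches)) {
    expect_length(batches[[b]], 16)
    tab <- table(factor(grp[batches[[b]]], levels = 1:4))
    expect_true(all(tab == 4))
    counts[b, ] <- tab
  }
  # each group supplies ~400 slots; small groups must repeat members
  expect_equal(colSums(counts), rep(400, 4))
  small_draws <- unlist(lapply(batches, function(ix) ix[grp[ix] == 2]))
  expect_gt(max(table(small_draws)), 1)   # with-replacement over-sampling
  # determinism
  b2 <- stratified_batches(hrs, g, 16, 100, seed = 5)
  expect_identical(batches, b2)
  # batch_size below the group count is rejected
  expect_error(stratified_batches(hrs, g, batch_size = 2, n_batches = 1),
               "batch_size")
})

test_that("uneven batch sizes distribute the remainder round-robin", {
  g <- hr_grouping(c(60, 80, 100))
  hrs <- c(runif(10, 60, 79), runif(10, 80, 99))
  batches <- stratified_batches(hrs, g, batch_size = 5, n_batches = 4,
                                seed = 1)
  grp <- g$group_of(hrs)
  for (b in batches) {
    tab <- table(factor(grp[b], levels = 1:2))
    expect_equal(sort(as.integer(tab)), c(2L, 3L))
  }
})

test_that("a default model overfits a single sample (capacity sanity)", {
  s <- gen_sample(synth_config(seed = 41, snr_db = Inf, drift_amp = 0,
                               artifact_rate = 0), 1)
  rec <- pulseband:::synth_to_record(s)
  net <- build_srrn(srrn_config(seed = 42))
  plan <- train_plan(phase1_epochs = 200, phase2_epochs = 1, batch_size = 1,
                     rng_seed = 1)
  # 1 step per epoch; phase 1 alone must reach loss < 0.01 within 500 steps
  fit <- train_srrn(net, list(rec, rec), plan, grouping = hr_grouping())
  expect_lt(min(fit$history$loss), 0.01)
})

test_that("training is reproducible under a fixed seed", {
  cfg <- synth_config(n_samples = 8, seed = 51)
  ds <- gen_dataset(cfg)
  recs <- lapply(ds$samples, pulseband:::synth_to_record)
  run <- function() {
    net <- build_srrn(srrn_config(seed = 52))
    train_srrn(net, recs, train_plan(phase1_epochs = 2, phase2_epochs = 1,
                                     batch_size = 4, rng_seed = 53),
               grouping = hr_grouping(c(40, 110, 180)))$history
  }
  expect_identical(run(), run())
})

test_that("phase-2 exposure is balanced across HR groups", {
  # count per-group slots delivered by the sampler over many batches
  g <- hr_grouping(c(50, 100, 150))
  hrs <- c(runif(90, 50, 99), runif(10, 100, 149))
  batches <- stratified_batches(hrs, g, batch_size = 10, n_batches = 200,
                                seed = 9)
  grp <- g$group_of(hrs)
  slots <- table(grp[unlist(batches)])
  expect_equal(as.integer(slots), c(1000L, 1000L))
})
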