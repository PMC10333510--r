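test_that("shape chain matches the canonical architecture", {
  sh <- compute_shapes(model_spec())
  expect_equal(sh$concat, c(250, 96))
  expect_equal(sh$pooled, c(83, 96))
  expect_equal(sh$gru, c(83, 32))
  expect_equal(sh$logits, 4)
  one <- compute_shapes(model_spec(kernel_lengths = 2, filters_per_scale = 1,
                                   pool_size = 1))
  expect_equal(one$concat, c(250, 1))
  expect_equal(one$pooled, c(250, 1))
  ten <- compute_shapes(model_spec(in_timepoints = 10, pool_size = 3,
                                   kernel_lengths = c(2, 4, 8)))
  expect_equal(ten$pooled[1], 3)
  expect_error(compute_shapes(model_spec(in_timepoints = 2, pool_size = 3)),
               "invalid spec")
})

test_that("multi-scale convolution matches hand expectations", {
  spec <- model_spec()
  params <- init_weights(spec, 1)
  zero <- lapply(params$conv, function(p) list(W = p$W * 0, b = p$b * 0))
  out <- multi_scale_conv(matrix(rnorm(64 * 250), 64, 250), zero)
  expect_equal(dim(out), c(250, 96))
  expect_true(all(out == 0))
  # default weights: feature dimension 96
  out2 <- multi_scale_conv(matrix(rnorm(64 * 250), 64, 250), params$conv)
  expect_equal(ncol(out2), 96)
  # 2-channel, 4-timepoint toy with a length-2 kernel of ones: interior
  # outputs are sliding sums over both channels
  epoch <- matrix(1:8, 2, 4)
  w <- list(list(W = matrix(1, 4, 1), b = 0))
  got <- multi_scale_conv(epoch, w)
  for (t in 2:4) expect_equal(got[t, 1], sum(epoch[, t - 1]) + sum(epoch[, t]))
  expect_equal(got[1, 1], sum(epoch[, 1]))  # left pad contributes zero
})

test_that("temporal max-pooling windows, truncation and constants behave", {
  expect_equal(max_pool_time(matrix(1:9, 9, 1), 3), matrix(c(3, 6, 9), 3, 1))
  cf <- matrix(5, 250, 4)
  expect_equal(max_pool_time(cf, 3), matrix(5, 83, 4))
  expect_equal(nrow(max_pool_time(matrix(0, 250, 96), 3)), 83)
  expect_error(max_pool_time(matrix(0, 2, 1), 3), "invalid input")
})

test_that("GRU fixed point at zero and hand-computed one-step case", {
  p0 <- list(Wx = matrix(0, 3, 6), Wh = matrix(0, 2, 6), b = rep(0, 6))
  hs <- gru_forward(matrix(rnorm(15), 5, 3), p0)
  expect_true(all(hs == 0))
  # hidden size 2, one step, hand-evaluated gate equations
  set.seed(42)
  p <- random_gru_params(3, 2)
  x <- rnorm(3)
  a <- drop(x %*% p$Wx) + p$b
  z <- 1 / (1 + exp(-a[1:2]))
  n <- tanh(a[5:6])            # h0 = 0: reset term vanishes
  expect_equal(drop(gru_forward(matrix(x, 1, 3), p)), z * n,
               tolerance = 1e-10)
  # default spec: hidden dimension 32
  spec <- model_spec(); params <- init_weights(spec, 2)
  hs32 <- gru_forward(matrix(rnorm(83 * 96), 83, 96), params$gru)
  expect_equal(dim(hs32), c(83, 32))
  expect_error(gru_forward(matrix(c(NA, 1:5), 2, 3), p), "non-finite")
})

test_that("head averages hidden states, exposes a 32-d feature, normalizes", {
  spec <- model_spec(); params <- init_weights(spec, 3)
  h <- matrix(rep(rnorm(32), each = 83), 83, 32)
  out <- head_forward(h, params$fc1, params$fc2)
  expect_equal(out$avg, h[1, ], tolerance = 1e-12)
  expect_length(out$avg, 32)
  expect_length(out$fc_hidden, 32)
  expect_equal(sum(out$probs), 1, tolerance = 1e-9)
  zero_fc <- list(W = matrix(0, 32, 4), b = rep(0, 4))
  out2 <- head_forward(matrix(rnorm(83 * 32), 83, 32), params$fc1, zero_fc)
  expect_equal(out2$probs, rep(0.25, 4), tolerance = 1e-12)
})

test_that("conv, pool and GRU agree with brute-force oracles over 100 seeded trials", {
  set.seed(2024)
  for (trial in 1:100) {
    C <- sample(2:5, 1); T <- sample(6:12, 1)
    k <- sample(c(1, 2, 3, 4), 1); F <- sample(1:4, 1)
    epoch <- matrix(rnorm(C * T), C, T)
    W <- matrix(rnorm(C * k * F), C * k, F); b <- rnorm(F)
    expect_equal(multi_scale_conv(epoch, list(list(W = W, b = b))),
                 oracle_conv(epoch, W, b), tolerance = 1e-6)
    fm <- matrix(rnorm(T * F), T, F)
    pool <- sample(1:3, 1)
    if (T >= pool)
      expect_equal(max_pool_time(fm, pool), oracle_pool(fm, pool),
                   tolerance = 1e-6)
    H <- sample(2:4, 1)
    p <- random_gru_params(F, H)
    seqm <- matrix(rnorm(T * F), T, F)
    expect_equal(gru_forward(seqm, p),
                 oracle_gru(seqm, p$Wx, p$Wh, p$b), tolerance = 1e-6)
  }
})

test_that("batched forward agrees with composing the exported single-epoch ops", {
  spec <- model_spec(n_classes = 3)
  params <- init_weights(spec, 7)
  set.seed(1)
  E <- array(rnorm(4 * 64 * 250), c(4, 64, 250))
  model <- structure(list(spec = spec, params = params,
                          classes = c("NC", "MDD", "SZ"),
                          montage = montage_1020()$name), class = "mcr_model")
  batch <- predict_probs(model, E)
  # the batched path computes in single precision; agreement is to float32
  # resolution, not machine epsilon
  for (i in 1:4) {
    fm <- multi_scale_conv(E[i, , ], params$conv)
    hs <- gru_forward(max_pool_time(fm, spec$pool_size), params$gru)
    hd <- head_forward(hs, params$fc1, params$fc2)
    expect_equal(unname(batch$probs[i, ]), hd$probs, tolerance = 1e-5)
    expect_equal(batch$avg[i, ], hd$avg, tolerance = 1e-5)
  }
})

test_that("shape chain agrees with the real forward pass across random specs", {
  set.seed(99)
  for (trial in 1:10) {
    spec <- model_spec(in_channels = sample(2:6, 1),
                       in_timepoints = sample(12:40, 1),
                       kernel_lengths = sort(sample(1:6, sample(1:3, 1))),
                       filters_per_scale = sample(1:5, 1),
                       pool_size = sample(1:3, 1),
                       gru_hidden = sample(2:6, 1),
                       fc_hidden = sample(2:6, 1),
                       n_classes = sample(2:4, 1))
    sh <- compute_shapes(spec)
    params <- init_weights(spec, trial)
    E <- array(rnorm(2 * spec$in_channels * spec$in_timepoints),
               c(2, spec$in_channels, spec$in_timepoints))
    fm <- multi_scale_conv(E[1, , ], params$conv)
    expect_equal(dim(fm), sh$concat)
    pooled <- max_pool_time(fm, spec$pool_size)
    expect_equal(dim(pooled), sh$pooled)
    hs <- gru_forward(pooled, params$gru)
    expect_equal(dim(hs), sh$gru)
    expect_length(head_forward(hs, params$fc1, params$fc2)$probs, sh$logits)
  }
})

test_that("channel permutation changes outputs unless kernels are permuted too", {
  spec <- model_spec(n_classes = 2)
  params <- init_weights(spec, 5)
  set.seed(3)
  epoch <- matrix(rnorm(64 * 250), 64, 250)
  perm <- sample(64)
  base <- multi_scale_conv(epoch, params$conv)
  permuted <- multi_scale_conv(epoch[perm, ], params$conv)
  expect_gt(max(abs(base - permuted)), 1e-3)
  conv_perm <- lapply(params$conv, function(p) {
    k <- nrow(p$W) / 64
    idx <- as.vector(vapply(0:(k - 1), function(j) j * 64 + perm,
                            numeric(64)))
    list(W = p$W[idx, , drop = FALSE], b = p$b)
  })
  expect_equal(multi_scale_conv(epoch[perm, ], conv_perm), base,
               tolerance = 1e-10)
})

test_that("softmax probabilities are positive and sum to one", {
  z <- matrix(c(-30, 0, 30, 5, 5, 5), 2, 3, byrow = TRUE)
  p <- mcrnn:::softmax_rows(z)
  expect_true(all(p > 0))
  expect_equal(rowSums(p), c(1, 1), tolerance = 1e-9)
  # extreme logits may underflow to 0 but must still normalize
  extreme <- mcrnn:::softmax_rows(matrix(c(-1000, 0, 1000), 1, 3))
  expect_equal(sum(extreme), 1, tolerance = 1e-9)
})

test_that("models round-trip through disk with shape validation", {
  spec <- model_spec(n_classes = 2)
  model <- structure(list(spec = spec, params = init_weights(spec, 1),
                          classes = c("NC", "SZ"),
                          montage = montage_1020()$name), class = "mcr_model")
  f <- tempfile(fileext = ".rds")
  save_model(model, f)
  back <- load_model(f)
  expect_equal(back$params, model$params)
  expect_equal(back$spec, model$spec)
  expect_equal(back$classes, model$classes)
  # corrupt a weight shape: loading must refuse
  broken <- readRDS(f)
  broken$params$gru$Wx <- broken$params$gru$Wx[, 1:10]
  saveRDS(broken, f)
  expect_error(load_model(f), "shape mismatch.*gru Wx")
})
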