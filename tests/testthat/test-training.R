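test_that("learning-rate schedule follows inverse-time decay", {
  ts <- train_spec()
  expect_equal(lr_schedule(0, ts), 0.001)
  expect_equal(lr_schedule(100, ts), 0.0005)
  ts0 <- train_spec(decay = 0)
  expect_equal(lr_schedule(0, ts0), 0.001)
  expect_equal(lr_schedule(500, ts0), 0.001)
  lrs <- vapply(0:50, lr_schedule, numeric(1), tspec = ts)
  expect_true(all(diff(lrs) <= 0))
  tm <- train_spec(decay_mode = "multiplicative")
  expect_equal(lr_schedule(2, tm), 0.001 * 0.99^2)
})

test_that("validation splits are sized, disjoint and reproducible", {
  es <- tiny_epoch_set(n_subjects = 10, epochs_per_subject = 100)
  ts <- train_spec(seed = 4)
  sp <- split_validation(es, ts)
  expect_equal(n_epochs(sp$train), 800)
  expect_equal(n_epochs(sp$val), 200)
  sp2 <- split_validation(es, ts)
  expect_identical(sp$val$epochs, sp2$val$epochs)
  # subject-level: 8/2 subjects and no subject on both sides
  tss <- train_spec(seed = 4, val_split_level = "subject")
  sps <- split_validation(es, tss)
  expect_length(unique(sps$val$subject_ids), 2)
  expect_length(unique(sps$train$subject_ids), 8)
  expect_length(intersect(sps$train$subject_ids, sps$val$subject_ids), 0)
  # both sides keep both classes
  expect_setequal(as.character(unique(sps$val$class_labels)), c("NC", "SZ"))
  expect_setequal(as.character(unique(sps$train$class_labels)), c("NC", "SZ"))
})

test_that("early stopping fires after `patience` stalled epochs; max_epochs caps", {
  es <- tiny_epoch_set(n_subjects = 4, epochs_per_subject = 4)
  sp <- split_validation(es, train_spec(seed = 1))
  # lr 0 freezes the network, so the validation loss never improves after
  # epoch 1 and the run must stop at exactly patience + 1 epochs
  ts <- train_spec(lr0 = 1e-12, max_epochs = 50, patience = 3, seed = 1,
                   batch_size = 8)
  fit <- fit_mcrnn(sp$train, sp$val, model_spec(n_classes = 2), ts)
  expect_equal(fit$stopped_epoch, 4)
  expect_equal(fit$reason, "patience")
  expect_equal(nrow(fit$history), 4)
  ts2 <- train_spec(max_epochs = 3, patience = 2, seed = 1, batch_size = 8)
  fit2 <- fit_mcrnn(sp$train, sp$val, model_spec(n_classes = 2), ts2)
  expect_lte(fit2$stopped_epoch, 3)
  expect_equal(nrow(fit2$history), fit2$stopped_epoch)
})

test_that("identical seeds reproduce identical training curves", {
  es <- tiny_epoch_set(n_subjects = 4, epochs_per_subject = 6)
  ts <- train_spec(max_epochs = 5, patience = 4, seed = 11, batch_size = 8)
  sp <- split_validation(es, ts)
  f1 <- fit_mcrnn(sp$train, sp$val, model_spec(n_classes = 2), ts)
  f2 <- fit_mcrnn(sp$train, sp$val, model_spec(n_classes = 2), ts)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("the training loss decreases over early epochs on learnable data", {
  # direct, strongly separable toy classes (planted constant oscillation)
  set.seed(5)
  n <- 48
  E <- array(rnorm(n * 64 * 250), c(n, 64, 250))
  lab <- rep(c("NC", "SZ"), each = n / 2)
  for (i in which(lab == "SZ"))
    E[i, 59, ] <- E[i, 59, ] + 3 * sin(2 * pi * 40 * (1:250) / 250)
  es <- epoch_set(E, paste0("s", seq_len(n)), lab)
  ts <- train_spec(max_epochs = 10, patience = 9, seed = 2, batch_size = 16)
  sp <- split_validation(es, ts)
  fit <- fit_mcrnn(sp$train, sp$val, model_spec(n_classes = 2), ts)
  h <- fit$history$train_loss
  expect_lt(mean(tail(h, 3)), mean(head(h, 3)))
})

test_that("stronger GRU-kernel regularization shrinks the kernel norm", {
  es <- tiny_epoch_set(n_subjects = 4, epochs_per_subject = 8)
  ts <- train_spec(max_epochs = 15, patience = 14, seed = 3, batch_size = 16)
  sp <- split_validation(es, ts)
  norms <- vapply(c(1, 100), function(mult) {
    ms <- model_spec(n_classes = 2, gru_l1 = 1e-4 * mult,
                     gru_l2 = 1e-4 * mult)
    fit <- fit_mcrnn(sp$train, sp$val, ms, ts)
    # norm of the last trained state, not the best-accuracy snapshot
    sqrt(sum(fit$final_params$gru$Wx^2))
  }, numeric(1))
  expect_lt(norms[2], norms[1])
})

test_that("label/class-count mismatches are rejected", {
  es <- tiny_epoch_set(n_subjects = 4, epochs_per_subject = 2)
  ts <- train_spec(max_epochs = 2, patience = 1, seed = 1)
  sp <- split_validation(es, ts)
  expect_error(fit_mcrnn(sp$train, sp$val, model_spec(n_classes = 4), ts),
               "2 levels.*4 classes")
})
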