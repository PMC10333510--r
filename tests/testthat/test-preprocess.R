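make_tone <- function(freq, fs = 1000, duration = 10, amp = 10) {
  n <- duration * fs
  tone <- amp * sin(2 * pi * freq * seq_len(n) / fs)
  data <- matrix(rep(tone, each = 64), 64, n)
  mcrnn:::new_recording("tone", "NC", data, fs)
}

test_that("downsampling checks the rate, halves nothing and counts samples", {
  rec <- simulate_recording("s", "NC", duration = 300, fs = 1000, seed = 1)
  expect_error(downsample(rec, 240), "1000.*240")
  out <- downsample(rec, 250)
  expect_equal(out$fs, 250)
  expect_equal(ncol(out$data), 75000)   # 300000 / 4
})

test_that("downsampling preserves passband tones and kills aliases", {
  t10 <- downsample(make_tone(10), 250)
  expect_lt(abs(sqrt(mean(t10$data[1, ]^2)) / (10 / sqrt(2)) - 1), 0.01)
  t200 <- make_tone(200)
  rms_in <- sqrt(mean(t200$data[1, ]^2))
  t200d <- downsample(t200, 250)
  expect_lt(sqrt(mean(t200d$data[1, ]^2)), 0.05 * rms_in)
})

test_that("band-pass removes DC, keeps 10 Hz, attenuates 100 Hz (zero phase)", {
  fs <- 250
  dc <- mcrnn:::new_recording("dc", "NC", matrix(50, 64, fs * 10), fs)
  out <- bandpass(dc)
  # steady-state attenuation (filtfilt edge transients excluded)
  expect_lt(sqrt(mean(out$data[1, 500:2000]^2)), 50 * 10^(-40 / 20))
  t10 <- bandpass(mcrnn:::new_recording("t", "NC",
    matrix(rep(10 * sin(2 * pi * 10 * seq_len(fs * 10) / fs), each = 64),
           64, fs * 10), fs))
  mid <- 500:2000
  expect_lt(abs(sqrt(mean(t10$data[1, mid]^2)) / (10 / sqrt(2)) - 1), 0.05)
  t100 <- bandpass(mcrnn:::new_recording("t", "NC",
    matrix(rep(10 * sin(2 * pi * 100 * seq_len(fs * 10) / fs), each = 64),
           64, fs * 10), fs))
  expect_lt(sqrt(mean(t100$data[1, mid]^2)), (10 / sqrt(2)) * 10^(-20 / 20))
  expect_error(bandpass(dc, 0.5, 130), "invalid band")
})

test_that("composite pipeline gain contract holds on probe sinusoids", {
  gain_at <- function(freq) {
    rec <- make_tone(freq, fs = 1000, duration = 8)
    out <- bandpass(downsample(rec, 250))
    mid <- 500:1500
    sqrt(mean(out$data[1, mid]^2)) / (10 / sqrt(2))
  }
  g10 <- gain_at(10)
  expect_gt(g10, 0.95); expect_lt(g10, 1.05)
  expect_lt(gain_at(100), 10^(-20 / 20))
})

test_that("clean 300-s recording yields 300 epochs of 64x250", {
  rec <- simulate_recording("s", "NC", duration = 300, fs = 1000, seed = 4)
  es <- preprocess_recording(rec)
  expect_equal(dim(es$epochs), c(300, 64, 250))
  expect_equal(unique(es$subject_ids), "s")
  expect_equal(as.character(unique(es$class_labels)), "NC")
})

test_that("too-short recordings yield an empty epoch set with a warning", {
  rec <- simulate_recording("s", "NC", duration = 0.5, fs = 250, seed = 1)
  expect_warning(es <- extract_epochs(rec), "shorter than one epoch")
  expect_equal(n_epochs(es), 0)
})

test_that("amplitude rejection drops exactly the contaminated epochs", {
  rec <- simulate_recording("s", "NC", duration = 300, fs = 1000, seed = 6)
  # 25 bursts placed in distinct, known epochs
  times <- (seq_len(25) * 11) + 0.3
  dirty <- inject_artifacts(rec, "amplitude_burst", rate = 0, seed = 2,
                            times = times)
  es <- preprocess_recording(dirty)
  expect_equal(n_epochs(es), 275)
  hit <- unique(floor(times) + 1)
  expect_length(intersect(attr(es, "kept"), hit), 0)
  # independent check: direct scan of the filtered recording
  filt <- bandpass(downsample(dirty, 250))
  peaks <- apply(abs(array(filt$data[, 1:75000], c(64, 250, 300))), 3, max)
  expect_equal(sum(peaks <= 100), 275)
})

test_that("lowering the rejection threshold never recovers epochs", {
  rec <- simulate_recording("s", "NC", duration = 60, fs = 250, seed = 8)
  dirty <- inject_artifacts(rec, "amplitude_burst", rate = 4, seed = 3)
  counts <- vapply(c(Inf, 200, 100, 50, 20),
                   function(th) n_epochs(extract_epochs(dirty,
                                                        reject_threshold = th)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("epoch windows tile the recording contiguously from sample zero", {
  rec <- simulate_recording("s", "NC", duration = 5, fs = 250, seed = 9)
  es <- extract_epochs(rec, reject_threshold = Inf)
  for (k in c(1, 3, 5)) {
    expect_equal(es$epochs[k, , ],
                 rec$data[, (k - 1) * 250 + 1:250])
  }
})

test_that("z-normalization standardizes rows and handles degenerate channels", {
  es <- tiny_epoch_set(2, 2, seed = 3)
  expect_identical(normalize_epochs(es, "none"), es)
  z <- normalize_epochs(es)
  m <- matrix(z$epochs, prod(dim(z$epochs)[1:2]), 250)
  expect_lt(max(abs(rowMeans(m))), 1e-9)
  expect_lt(max(abs(apply(m, 1, stats::sd) - 1)), 1e-6)
  es$epochs[1, 5, ] <- 7  # constant channel
  expect_warning(z2 <- normalize_epochs(es), "zero-variance")
  expect_true(all(z2$epochs[1, 5, ] == 0))
})
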