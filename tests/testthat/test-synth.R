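test_that("montage has 64 unique labels including the discriminative set", {
  m <- montage_1020()
  expect_equal(nrow(m), 64)
  expect_equal(anyDuplicated(m$name), 0)
  expect_true(all(c("O1", "O2", "PO4", "P3", "P7", "P8", "Fp1", "F8",
                    "CPz") %in% m$name))
  expect_equal(m$index, 0:63)
})

test_that("cohort generation conserves class counts and validates labels", {
  recs <- simulate_cohort(c(BP = 72, MDD = 138, SZ = 70, NC = 47),
                          duration = 0.5, seed = 3)
  expect_length(recs, 327)
  counts <- table(vapply(recs, `[[`, "", "class_label"))
  expect_equal(counts[["BP"]], 72)
  expect_equal(counts[["MDD"]], 138)
  expect_equal(counts[["SZ"]], 70)
  expect_equal(counts[["NC"]], 47)
  bad <- list(SZ = class_signature("SZ", list(
    signature_component("NOPE", 10, 2, 5))))
  expect_error(simulate_cohort(c(SZ = 1), duration = 1, signatures = bad,
                               seed = 1),
               "unknown channel label.*NOPE")
  expect_error(simulate_cohort(c(SZ = 1), duration = 1, seed = 1,
                               n_per_class = c(XX = 1)),
               "n_per_class")
})

test_that("zero-amplitude, zero-noise configuration yields all-zero data", {
  sigs <- list(NC = class_signature("NC", list(
    signature_component("O1", 10, 2, 0))))
  recs <- simulate_cohort(c(NC = 2), duration = 1, signatures = sigs,
                          noise = list(exponent = 1, background_rms = 0,
                                       white_rms = 0),
                          seed = 5)
  for (r in recs) expect_true(all(r$data == 0))
})

test_that("identical seeds give bit-identical recordings, different seeds differ", {
  a <- simulate_cohort(c(NC = 2, SZ = 1), duration = 1, seed = 11)
  b <- simulate_cohort(c(NC = 2, SZ = 1), duration = 1, seed = 11)
  d <- simulate_cohort(c(NC = 2, SZ = 1), duration = 1, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a[[1]]$data, d[[1]]$data))
  # counter-scheme: first NC subject unchanged when the cohort grows
  bigger <- simulate_cohort(c(NC = 3, SZ = 1), duration = 1, seed = 11)
  expect_identical(a[[1]]$data, bigger[[1]]$data)
})

test_that("a planted component peaks at its frequency on target channels only", {
  sigs <- list(NC = class_signature("NC", list(
    signature_component("O1", freq = 10, bandwidth = 2, amplitude = 30))))
  rec <- simulate_cohort(c(NC = 1), duration = 20, fs = 250,
                         signatures = sigs, seed = 7)[[1]]
  pk <- function(ch) {
    sp <- stats::spec.pgram(rec$data[match(ch, rec$montage), ],
                            spans = 5, taper = 0, plot = FALSE)
    freq_hz <- sp$freq * 250
    band <- freq_hz > 2 & freq_hz < 100
    freq_hz[band][which.max(sp$spec[band])]
  }
  expect_lt(abs(pk("O1") - 10), 0.5)
  expect_gt(abs(pk("Cz") - 10), 2)   # no alpha peak off-target
})

test_that("band power off target stays at background level (spatial specificity)", {
  sigs <- list(SZ = class_signature("SZ", list(
    signature_component(c("O1", "P3"), freq = 40, bandwidth = 4,
                        amplitude = 20))))
  rec <- simulate_cohort(c(SZ = 1), duration = 10, fs = 250,
                         signatures = sigs, seed = 13)[[1]]
  bandpow <- function(i) {
    sp <- Mod(stats::fft(rec$data[i, ]))^2
    f <- (seq_along(sp) - 1) / length(sp) * 250   # one-sided bins below Nyquist
    mean(sp[f >= 38 & f <= 42])
  }
  pows <- vapply(seq_len(64), bandpow, numeric(1))
  targets <- match(c("O1", "P3"), rec$montage)
  bg <- pows[-targets]
  # targets leap out; no non-target channel looks like a planted component
  expect_true(all(pows[targets] > mean(bg) + 5 * stats::sd(bg)))
  expect_lt(max(bg), mean(bg) + 4 * stats::sd(bg))
})

test_that("artifact injection is seeded, rate-faithful and above threshold", {
  rec <- simulate_recording("s1", "NC", duration = 300, fs = 250, seed = 2)
  expect_error(inject_artifacts(rec, rate = -1), "rate")
  same <- inject_artifacts(rec, "amplitude_burst", rate = 6, seed = 4)
  same2 <- inject_artifacts(rec, "amplitude_burst", rate = 6, seed = 4)
  expect_identical(same, same2)
  n_ev <- nrow(same$artifacts)
  expect_gt(n_ev, 15)          # ~30 expected on 300 s at 6/min
  expect_lt(n_ev, 50)
  set.seed(4)
  expect_equal(n_ev, stats::rpois(1, 6 * 300 / 60))  # exact seeded count
  # rate 0 is the identity
  clean <- inject_artifacts(rec, "amplitude_burst", rate = 0, seed = 4)
  expect_equal(clean$data, rec$data)
  # each burst drives some sample past the +/-100 uV rejection threshold
  for (t0 in same$artifacts$onset) {
    idx <- floor(t0 * 250) + seq_len(round(0.15 * 250))
    expect_gt(max(abs(same$data[, idx])), 100)
  }
})

test_that("blink artifacts land on frontopolar channels", {
  rec <- simulate_recording("s1", "NC", duration = 10, fs = 250, seed = 2)
  blinked <- inject_artifacts(rec, "eog_blink", rate = 0, seed = 1, times = 2)
  moved <- which(rowSums(abs(blinked$data - rec$data)) > 0)
  expect_setequal(rec$montage[moved], c("Fp1", "Fpz", "Fp2"))
  expect_gt(max(abs(blinked$data[moved[1], ])), 100)
})
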