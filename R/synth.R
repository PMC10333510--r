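#' @keywords internal
new_recording <- function(subject_id, class_label, data, fs,
                          montage = montage_1020()$name) {
  stopifnot(is.matrix(data), nrow(data) == length(montage))
  structure(list(subject_id = subject_id,
                 class_label = class_label,
                 data = data, fs = fs, montage = montage),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s (%s): %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$class_label, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

# Coloured (1/f^alpha) Gaussian noise via spectral shaping. The spectrum
# flattens below `knee` Hz (scalp EEG spectra plateau near 1 Hz rather than
# diverging); DC is zeroed so the series is mean-free; output scaled to the
# requested RMS.
#' @keywords internal
noise_oneoverf <- function(n, fs, exponent = 1, rms = 10, knee = 1) {
  if (rms == 0) return(numeric(n))
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(0, seq_len(n - 1)) / n * fs
  f <- pmin(f, fs - f)                      # two-sided |frequency|
  shape <- ifelse(f > 0, pmax(f, knee)^(-exponent / 2), 0)
  y <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  y * rms / sqrt(mean(y^2))
}

# Narrow-band Gaussian process: white noise filtered with a Gaussian
# spectral window centred on `freq` (sd = bandwidth/2), scaled to `rms`.
#' @keywords internal
noise_narrowband <- function(n, fs, freq, bandwidth = 2, rms = 1) {
  if (rms == 0) return(numeric(n))
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(0, seq_len(n - 1)) / n * fs
  f <- pmin(f, fs - f)
  shape <- exp(-0.5 * ((f - freq) / (bandwidth / 2))^2)
  y <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  y * rms / sqrt(mean(y^2))
}

#' Simulate one resting-state EEG recording
#'
#' Generates a continuous multichannel recording as 1/f^alpha background
#' plus a white-noise floor on every channel, with the class signature's
#' narrow-band components superimposed on their target channels only. The
#' data are treated as already referenced to CPz; units are microvolts.
#'
#' @param subject_id subject identifier string.
#' @param class_label diagnostic label (see [class_levels()]).
#' @param signature a [class_signature()] or `NULL` for background only.
#' @param duration recording length in seconds (default 300 s, i.e. the
#'   5-minute resting-state session).
#' @param fs sampling rate in Hz (default 1000).
#' @param noise list with elements `exponent` (spectral slope alpha,
#'   default 1), `background_rms` (microvolt, default 10) and `white_rms`
#'   (broadband floor, default 1).
#' @param montage channel label vector (default [montage_1020()]).
#' @param seed integer seed; the recording is a pure function of its
#'   arguments.
#' @return An `eeg_recording` object.
#' @export
simulate_recording <- function(subject_id, class_label, signature = NULL,
                               duration = 300, fs = 1000,
                               noise = list(exponent = 1, background_rms = 10,
                                            white_rms = 1),
                               montage = montage_1020()$name, seed = 1L) {
  stopifnot(duration > 0, fs > 0)
  n <- round(duration * fs)
  set.seed(seed)
  nchan <- length(montage)
  data <- matrix(0, nchan, n)
  bg <- noise$background_rms %||% 10
  wh <- noise$white_rms %||% 1
  ex <- noise$exponent %||% 1
  for (c in seq_len(nchan)) {
    ch <- noise_oneoverf(n, fs, ex, bg)
    if (wh > 0) ch <- ch + stats::rnorm(n, sd = wh)
    data[c, ] <- ch
  }
  if (!is.null(signature)) {
    for (co in signature$components) {
      check_montage_labels(co$channels, montage)
      for (lab in co$channels) {
        i <- match(lab, montage)
        data[i, ] <- data[i, ] +
          noise_narrowband(n, fs, co$freq, co$bandwidth, co$amplitude)
      }
    }
  }
  new_recording(subject_id, class_label, data, fs, montage)
}

#' Simulate a labelled multi-subject EEG cohort
#'
#' Produces one recording per subject with class-conditional planted
#' signatures. The default cohort sizes reproduce the study regime of 327
#' subjects: BP = 72, MDD = 138, SZ = 70, NC = 47. Each subject's random
#' stream is derived from the master seed by a fixed counter scheme
#' (`seed + 100000 * class_code + subject_index`), so shrinking or growing
#' one class never reshuffles the other subjects.
#'
#' @param n_per_class named integer vector of cohort sizes; names must be
#'   a subset of [class_levels()].
#' @param duration,fs,noise,montage as in [simulate_recording()].
#' @param signatures named list of [class_signature()] objects (defaults to
#'   [default_signatures()]). Every simulated class must have an entry.
#' @param artifact_rate transient artifact events per minute superimposed
#'   on every recording (0 = clean).
#' @param artifact_kind passed to [inject_artifacts()] when
#'   `artifact_rate > 0`.
#' @param seed master integer seed (required).
#' @return List of `eeg_recording` objects, grouped by class in the order
#'   of `n_per_class`.
#' @examples
#' recs <- simulate_cohort(c(NC = 2, SZ = 2), duration = 2, seed = 42)
#' length(recs)
#' @export
simulate_cohort <- function(n_per_class = c(BP = 72, MDD = 138, SZ = 70, NC = 47),
                            duration = 300, fs = 1000,
                            signatures = default_signatures(),
                            noise = list(exponent = 1, background_rms = 10,
                                         white_rms = 1),
                            artifact_rate = 0,
                            artifact_kind = "amplitude_burst",
                            montage = montage_1020()$name,
                            seed) {
  if (missing(seed)) stop("simulate_cohort() requires an explicit seed",
                          call. = FALSE)
  stopifnot(all(n_per_class >= 0), duration > 0)
  classes <- names(n_per_class)
  if (is.null(classes) || !all(classes %in% class_levels()))
    stop("n_per_class must be named with labels among ",
         paste(class_levels(), collapse = "/"), call. = FALSE)
  # validate signature channel labels up front
  for (cl in classes) {
    sg <- signatures[[cl]]
    if (!is.null(sg))
      for (co in sg$components) check_montage_labels(co$channels, montage)
  }
  recs <- list()
  for (cl in classes) {
    code <- match(cl, class_levels())
    for (j in seq_len(n_per_class[[cl]])) {
      sseed <- as.integer(seed + 100000L * code + j)
      rec <- simulate_recording(sprintf("%s-%03d", cl, j), cl,
                                signatures[[cl]], duration, fs, noise,
                                montage, seed = sseed)
      if (artifact_rate > 0)
        rec <- inject_artifacts(rec, artifact_kind, artifact_rate,
                                seed = sseed + 50000L)
      recs[[length(recs) + 1L]] <- rec
    }
  }
  recs
}

#' Superimpose transient artifacts on a recording
#'
#' Adds stereotyped high-amplitude transients so the preprocessing
#' amplitude-rejection rule has something to reject. `eog_blink` events are
#' 0.3-s half-sine deflections (300 microvolt peak) on the frontopolar
#' channels; `amplitude_burst` events are 0.15-s Hann-windowed 10 Hz bursts
#' (250 microvolt peak) on three random channels. Both exceed the default
#' +/-100 microvolt rejection threshold and survive the 0.5-70 Hz band-pass.
#'
#' @param rec an `eeg_recording`.
#' @param kind `"eog_blink"` or `"amplitude_burst"`.
#' @param rate expected events per minute (Poisson schedule); must be >= 0.
#' @param seed integer seed controlling the event schedule.
#' @param times optional explicit onset times (seconds), overriding the
#'   Poisson schedule (used to place events in known epochs).
#' @return A modified copy of `rec`; the event schedule is attached as the
#'   data.frame `rec$artifacts` (columns `onset`, `kind`).
#' @export
inject_artifacts <- function(rec, kind = c("amplitude_burst", "eog_blink"),
                             rate = 6, seed = 1L, times = NULL) {
  kind <- match.arg(kind)
  if (rate < 0) stop("artifact rate must be >= 0", call. = FALSE)
  out <- rec
  dur <- ncol(rec$data) / rec$fs
  set.seed(seed)
  if (is.null(times)) {
    n_ev <- if (rate == 0) 0L else stats::rpois(1, rate * dur / 60)
    times <- if (n_ev > 0) sort(stats::runif(n_ev, 0, dur - 0.5)) else numeric(0)
  }
  if (length(times) == 0) {
    out$artifacts <- data.frame(onset = numeric(0), kind = character(0))
    return(out)
  }
  fs <- rec$fs
  for (t0 in times) {
    i0 <- floor(t0 * fs) + 1L
    if (kind == "eog_blink") {
      len <- round(0.3 * fs)
      idx <- i0:min(i0 + len - 1L, ncol(out$data))
      pulse <- 300 * sin(pi * seq_along(idx) / length(idx))
      chans <- intersect(c("Fp1", "Fpz", "Fp2"), rec$montage)
      for (lab in chans) {
        i <- match(lab, rec$montage)
        out$data[i, idx] <- out$data[i, idx] + pulse
      }
    } else {
      len <- round(0.15 * fs)
      idx <- i0:min(i0 + len - 1L, ncol(out$data))
      w <- 0.5 - 0.5 * cos(2 * pi * seq_along(idx) / length(idx))
      burst <- 250 * w * sin(2 * pi * 10 * seq_along(idx) / fs)
      chans <- sample(nrow(out$data), 3)
      for (i in chans) out$data[i, idx] <- out$data[i, idx] + burst
    }
  }
  out$artifacts <- data.frame(onset = times, kind = kind)
  out
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
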