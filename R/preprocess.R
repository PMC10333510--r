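#' Anti-aliased downsampling
#'
#' Low-pass filters every channel (zero-phase, 6th-order Butterworth with
#' cutoff at 0.8 of the new Nyquist frequency) and decimates by the integer
#' factor `fs / target_fs`.
#'
#' @param rec an `eeg_recording`.
#' @param target_fs new sampling rate in Hz; must divide `rec$fs` exactly.
#' @return The downsampled `eeg_recording`; the sample count is
#'   `floor(n / factor)`.
#' @export
downsample <- function(rec, target_fs = 250) {
  if (rec$fs %% target_fs != 0)
    stop(sprintf("unsupported rate conversion: %g Hz -> %g Hz is not an integer factor",
                 rec$fs, target_fs), call. = FALSE)
  factor <- rec$fs / target_fs
  if (factor == 1) return(rec)
  bf <- signal::butter(6, 0.8 * target_fs / rec$fs, type = "low")
  n_out <- floor(ncol(rec$data) / factor)
  keep <- seq(1, by = factor, length.out = n_out)
  out <- rec
  filtered <- t(apply(rec$data, 1, function(x) signal::filtfilt(bf, x)))
  out$data <- filtered[, keep, drop = FALSE]
  out$fs <- target_fs
  out
}

#' Zero-phase band-pass filter
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass,
#' implemented as cascaded order-4 high-pass and order-4 low-pass sections
#' for numerical stability at the low band edge.
#'
#' @param rec an `eeg_recording`.
#' @param lo,hi band edges in Hz (defaults 0.5 and 70); requires
#'   `0 < lo < hi < fs/2`.
#' @return The filtered `eeg_recording`.
#' @export
bandpass <- function(rec, lo = 0.5, hi = 70) {
  nyq <- rec$fs / 2
  if (!(lo > 0 && lo < hi && hi < nyq))
    stop(sprintf("invalid band [%g, %g] Hz for fs %g Hz (need 0 < lo < hi < fs/2)",
                 lo, hi, rec$fs), call. = FALSE)
  bh <- signal::butter(4, lo / nyq, type = "high")
  bl <- signal::butter(4, hi / nyq, type = "low")
  out <- rec
  out$data <- t(apply(rec$data, 1, function(x)
    signal::filtfilt(bl, signal::filtfilt(bh, x))))
  out
}

#' Extract fixed-length epochs with amplitude rejection
#'
#' Cuts the recording into consecutive non-overlapping windows starting at
#' sample 0 (epoch `k` covers samples `[k*w, (k+1)*w)`, 0-based) and drops
#' every epoch whose absolute amplitude exceeds `reject_threshold` on any
#' channel — the amplitude-threshold artifact rejection rule.
#'
#' @param rec an `eeg_recording` (expected at 250 Hz after [downsample()]).
#' @param epoch_s epoch length in seconds (default 1).
#' @param reject_threshold rejection threshold in microvolts (default 100);
#'   `Inf` disables rejection.
#' @return An `epoch_set`; the original epoch indices of the survivors are
#'   attached as attribute `"kept"`. A recording shorter than one epoch
#'   yields an empty set with a warning.
#' @export
extract_epochs <- function(rec, epoch_s = 1, reject_threshold = 100) {
  w <- epoch_s * rec$fs
  if (abs(w - round(w)) > 1e-9)
    stop("epoch length times sampling rate must be an integer number of samples",
         call. = FALSE)
  w <- as.integer(round(w))
  nchan <- nrow(rec$data)
  n_ep <- floor(ncol(rec$data) / w)
  if (n_ep == 0) {
    warning("recording shorter than one epoch; returning empty epoch set")
    es <- epoch_set(array(0, c(0, nchan, w)), character(0),
                    factor(character(0), levels = class_levels()),
                    rec$fs, rec$montage)
    attr(es, "kept") <- integer(0)
    return(es)
  }
  trimmed <- rec$data[, seq_len(n_ep * w), drop = FALSE]
  # (channel, sample-in-epoch, epoch) -> (epoch, channel, sample)
  arr <- aperm(array(trimmed, c(nchan, w, n_ep)), c(3, 1, 2))
  peak <- apply(abs(arr), 1, max)
  keep <- which(peak <= reject_threshold)
  es <- epoch_set(arr[keep, , , drop = FALSE],
                  rep(rec$subject_id, length(keep)),
                  rep(rec$class_label, length(keep)),
                  rec$fs, rec$montage)
  attr(es, "kept") <- keep
  es
}

#' Normalize epochs
#'
#' `per_channel_z` standardizes every channel of every epoch to mean 0 and
#' SD 1 over its own samples (the model-input scaling used by default);
#' `none` is the identity. A zero-variance channel cannot be standardized
#' and is set to all zeros with a warning.
#'
#' @param es an `epoch_set`.
#' @param mode `"per_channel_z"` or `"none"`.
#' @return The normalized `epoch_set`.
#' @export
normalize_epochs <- function(es, mode = c("per_channel_z", "none")) {
  mode <- match.arg(mode)
  if (mode == "none" || n_epochs(es) == 0) return(es)
  d <- dim(es$epochs)
  m <- matrix(es$epochs, d[1] * d[2], d[3])   # row = (epoch, channel)
  mu <- rowMeans(m)
  sd <- sqrt(pmax(rowMeans(m * m) - mu^2, 0) * d[3] / (d[3] - 1))
  flat <- sd < 1e-12
  if (any(flat)) {
    warning(sum(flat), " zero-variance channel row(s) set to 0 during z-scoring")
    sd[flat] <- 1
  }
  m <- (m - mu) / sd
  if (any(flat)) m[flat, ] <- 0
  out <- es
  out$epochs <- array(m, d)
  out
}

#' Full preprocessing chain for one recording
#'
#' [downsample()] to `target_fs`, [bandpass()] to `band`, [extract_epochs()]
#' with amplitude rejection, then [normalize_epochs()].
#'
#' @param rec an `eeg_recording`.
#' @param target_fs downsampling target (Hz).
#' @param band band-pass edges in Hz.
#' @param epoch_s epoch length (s).
#' @param reject_threshold amplitude rejection threshold (microvolt).
#' @param normalize normalization mode (see [normalize_epochs()]).
#' @return An `epoch_set`.
#' @export
preprocess_recording <- function(rec, target_fs = 250, band = c(0.5, 70),
                                 epoch_s = 1, reject_threshold = 100,
                                 normalize = "per_channel_z") {
  rec <- downsample(rec, target_fs)
  rec <- bandpass(rec, band[1], band[2])
  es <- extract_epochs(rec, epoch_s, reject_threshold)
  normalize_epochs(es, normalize)
}

#' Preprocess a cohort of recordings into one epoch set
#'
#' @param recs list of `eeg_recording` objects.
#' @param ... passed to [preprocess_recording()].
#' @return A combined `epoch_set` with contiguous per-subject blocks.
#' @export
preprocess_cohort <- function(recs, ...) {
  bind_epoch_sets(lapply(recs, preprocess_recording, ...))
}
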