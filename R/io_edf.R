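# Minimal 16-bit EDF writer/reader (standard header, field-major signal
# headers, one 1-second data record per block, little-endian int16 data).
# Covers exactly what the package needs: continuous multichannel recordings
# with physical units in microvolts.

#' @keywords internal
pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = -width)  # left-aligned, space-padded
}

#' Write a recording to EDF
#'
#' Standard EDF with 16-bit samples; per-channel physical limits are set
#' symmetrically to the channel's peak amplitude, so the quantization step
#' is `2 * max|x| / 65535` microvolts. The subject id and class label are
#' stored in the patient-identification field. Samples beyond the last
#' whole 1-s record are dropped.
#'
#' @param rec an `eeg_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer needs an integer sampling rate")
  ns <- nrow(rec$data)
  n_rec <- floor(ncol(rec$data) / fs)
  if (n_rec < 1) stop("recording shorter than one EDF record (1 s)")
  pm <- apply(abs(rec$data), 1, max)
  pm[pm == 0] <- 1
  # physical limits as printed in the 8-char header fields (7 chars + sign);
  # quantization uses the printed value so writer and reader agree exactly
  fmt_phys <- function(v) {
    for (d in 6:1) {
      s <- sprintf("%.*g", d, v)
      if (nchar(s) <= 7) return(s)
    }
    "1"
  }
  pm_str <- vapply(pm, fmt_phys, "")
  pm_used <- as.numeric(pm_str)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(pad_field("0", 8))
  wr(pad_field(paste(rec$subject_id, rec$class_label), 80))
  wr(pad_field("mcrnn synthetic EEG", 80))
  wr(pad_field("01.01.00", 8)); wr(pad_field("00.00.00", 8))
  wr(pad_field(256 * (ns + 1), 8))
  wr(pad_field("", 44))
  wr(pad_field(n_rec, 8))
  wr(pad_field("1", 8))
  wr(pad_field(ns, 4))
  wr(paste0(vapply(rec$montage, pad_field, "", width = 16), collapse = ""))
  wr(paste0(rep(pad_field("AgAgCl electrode", 80), ns), collapse = ""))
  wr(paste0(rep(pad_field("uV", 8), ns), collapse = ""))
  wr(paste0(vapply(paste0("-", pm_str), pad_field, "", width = 8),
            collapse = ""))
  wr(paste0(vapply(pm_str, pad_field, "", width = 8), collapse = ""))
  wr(paste0(rep(pad_field("-32768", 8), ns), collapse = ""))
  wr(paste0(rep(pad_field("32767", 8), ns), collapse = ""))
  wr(paste0(rep(pad_field("", 80), ns), collapse = ""))
  wr(paste0(rep(pad_field(fs, 8), ns), collapse = ""))
  wr(paste0(rep(pad_field("", 32), ns), collapse = ""))
  scale <- 65535 / (2 * pm_used)
  for (r in seq_len(n_rec)) {
    idx <- (r - 1) * fs + seq_len(fs)
    block <- rec$data[, idx, drop = FALSE]
    dig <- round((block + pm_used) * scale) - 32768
    dig <- pmin(pmax(dig, -32768), 32767)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' @param path EDF file path.
#' @return An `eeg_recording` with data in physical units (microvolts).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8)                                   # version
  patient <- rd(80)
  rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fld(16)
  fld(80)                                 # transducer
  fld(8)                                  # physical dimension
  pmin_ <- as.numeric(fld(8))
  pmax_ <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8))
  dmax <- as.numeric(fld(8))
  fld(80)                                 # prefiltering
  spr <- as.integer(fld(8))
  fld(32)                                 # reserved
  stopifnot(length(unique(spr)) == 1)
  fs <- spr[1] / rec_dur
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr[1], size = 2, signed = TRUE,
                   endian = "little")
    block <- matrix(raw, nrow = spr[1], ncol = ns)   # sample-major per signal
    data[, (r - 1) * spr[1] + seq_len(spr[1])] <- t(block)
  }
  for (i in seq_len(ns))
    data[i, ] <- (data[i, ] - dmin[i]) / (dmax[i] - dmin[i]) *
      (pmax_[i] - pmin_[i]) + pmin_[i]
  parts <- strsplit(patient, " +")[[1]]
  subject_id <- if (length(parts) >= 1) parts[1] else "unknown"
  label <- if (length(parts) >= 2 && parts[2] %in% class_levels()) parts[2] else NA
  new_recording(subject_id, label, data, fs, montage = labels)
}
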