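#' Write a recording to disk
#'
#' `format = "array"` stores the data matrix losslessly (RDS) with a JSON
#' sidecar (`<path>.json`) carrying subject id, class label, sampling rate
#' and montage order; `format = "edf"` writes standard 16-bit EDF.
#'
#' @param rec an `eeg_recording`.
#' @param path destination path (conventionally `.rds` or `.edf`).
#' @param format `"array"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("array", "edf")) {
  format <- match.arg(format)
  if (format == "edf") return(write_edf(rec, path))
  saveRDS(rec$data, path)
  jsonlite::write_json(list(subject_id = rec$subject_id,
                            class_label = rec$class_label,
                            fs = rec$fs, montage = rec$montage),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a recording from disk
#'
#' Reads either format written by [write_recording()]. By default the
#' 64-channel contract is enforced (the network's first-layer kernels span
#' exactly 64 rows); `strict = FALSE` pads missing channels with zeros or
#' drops extras, with a warning (experimental).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"array"` or `"edf"`.
#' @param strict enforce the expected channel count (default TRUE).
#' @param expected_channels contract size (default 64).
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, format = c("auto", "array", "edf"),
                           strict = TRUE, expected_channels = 64L) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "array"
  rec <- if (format == "edf") {
    read_edf(path)
  } else {
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    new_recording(meta$subject_id, meta$class_label, readRDS(path), meta$fs,
                  montage = meta$montage)
  }
  nch <- nrow(rec$data)
  if (nch != expected_channels) {
    if (strict)
      stop(sprintf("expected %d channels, found %d in %s",
                   expected_channels, nch, path), call. = FALSE)
    warning(sprintf("channel count %d != %d; %s (lenient mode)",
                    nch, expected_channels,
                    if (nch > expected_channels) "dropping extras"
                    else "padding with zeros"))
    if (nch > expected_channels) {
      rec$data <- rec$data[seq_len(expected_channels), , drop = FALSE]
      rec$montage <- rec$montage[seq_len(expected_channels)]
    } else {
      pad <- expected_channels - nch
      rec$data <- rbind(rec$data, matrix(0, pad, ncol(rec$data)))
      rec$montage <- c(rec$montage, sprintf("PAD%d", seq_len(pad)))
    }
  }
  rec
}

#' Write an epoch set (array container + JSON sidecar)
#'
#' @param es an `epoch_set`.
#' @param path destination `.rds` path; provenance (subjects, labels,
#'   montage, fs and any preprocessing parameters in `params`) goes to
#'   `<path>.json`.
#' @param params optional named list recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(es, path, params = NULL) {
  saveRDS(es$epochs, path)
  jsonlite::write_json(list(subject_ids = es$subject_ids,
                            class_labels = as.character(es$class_labels),
                            levels = levels(es$class_labels),
                            fs = es$fs, montage = es$montage,
                            params = params),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an epoch set written by [write_epochs()]
#' @param path `.rds` path.
#' @return An `epoch_set`.
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  epoch_set(readRDS(path), meta$subject_ids, meta$class_labels,
            fs = meta$fs, montage = meta$montage, levels = meta$levels)
}

#' Save a trained model
#'
#' Single portable file: the architecture is embedded as a JSON header next
#' to the weights, and [load_model()] re-validates every weight shape
#' against it.
#'
#' @param model an `mcr_model`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  s <- unclass(model$spec)
  s$dropout <- as.list(s$dropout)   # keep the rate names through JSON
  spec_json <- jsonlite::toJSON(s, auto_unbox = TRUE, digits = NA)
  saveRDS(list(spec_json = as.character(spec_json), params = model$params,
               classes = model$classes, montage = model$montage), path)
  invisible(path)
}

#' Load a model saved by [save_model()]
#' @param path file path.
#' @return An `mcr_model`; errors if any weight matrix disagrees with the
#'   embedded architecture header.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  sj <- jsonlite::fromJSON(obj$spec_json)
  spec <- model_spec(in_channels = sj$in_channels,
                     in_timepoints = sj$in_timepoints,
                     kernel_lengths = sj$kernel_lengths,
                     filters_per_scale = sj$filters_per_scale,
                     pool_size = sj$pool_size, gru_hidden = sj$gru_hidden,
                     fc_hidden = sj$fc_hidden, n_classes = sj$n_classes,
                     dropout = unlist(sj$dropout),
                     gru_l1 = sj$gru_l1, gru_l2 = sj$gru_l2)
  p <- obj$params
  featdim <- spec$filters_per_scale * length(spec$kernel_lengths)
  expect_dim <- function(x, d, what) {
    if (!identical(dim(x), as.integer(d)))
      stop(sprintf("weight shape mismatch for %s: stored %s, spec needs %s",
                   what, paste(dim(x), collapse = "x"),
                   paste(d, collapse = "x")), call. = FALSE)
  }
  for (i in seq_along(spec$kernel_lengths)) {
    k <- spec$kernel_lengths[i]
    expect_dim(p$conv[[i]]$W, c(spec$in_channels * k, spec$filters_per_scale),
               paste0("conv k=", k))
  }
  expect_dim(p$gru$Wx, c(featdim, 3 * spec$gru_hidden), "gru Wx")
  expect_dim(p$gru$Wh, c(spec$gru_hidden, 3 * spec$gru_hidden), "gru Wh")
  expect_dim(p$fc1$W, c(spec$gru_hidden, spec$fc_hidden), "fc1")
  expect_dim(p$fc2$W, c(spec$fc_hidden, spec$n_classes), "fc2")
  structure(list(spec = spec, params = p, classes = obj$classes,
                 montage = obj$montage), class = "mcr_model")
}
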