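#' Construct an epoch set
#'
#' The model-ready container: a stack of fixed-length epochs with
#' per-epoch subject and label provenance. Epochs are stored as an
#' `n_epochs x n_channels x n_samples` array (the canonical model input is
#' `n x 64 x 250` at 250 Hz).
#'
#' @param epochs 3-D numeric array, `n x channels x samples`.
#' @param subject_ids character vector, length `n`.
#' @param class_labels factor or character vector, length `n`; coerced to a
#'   factor (levels default to the order of [class_levels()] restricted to
#'   labels present, so label encoding is stable across subsets).
#' @param fs sampling rate of the epochs in Hz.
#' @param montage channel labels (length = `dim(epochs)[2]`).
#' @param levels optional explicit factor levels for the labels.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, subject_ids, class_labels, fs = 250,
                      montage = montage_1020()$name, levels = NULL) {
  stopifnot(length(dim(epochs)) == 3)
  n <- dim(epochs)[1]
  stopifnot(length(subject_ids) == n, length(class_labels) == n,
            dim(epochs)[2] == length(montage))
  if (is.null(levels)) {
    if (is.factor(class_labels)) levels <- base::levels(class_labels)
    else levels <- intersect(class_levels(), unique(class_labels))
    if (length(levels) == 0) levels <- sort(unique(as.character(class_labels)))
  }
  structure(list(epochs = epochs,
                 subject_ids = as.character(subject_ids),
                 class_labels = factor(as.character(class_labels), levels = levels),
                 fs = fs, montage = montage),
            class = "epoch_set")
}

#' Number of epochs in an epoch set
#' @param es an `epoch_set`.
#' @export
n_epochs <- function(es) dim(es$epochs)[1]

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat("  subjects:", length(unique(x$subject_ids)),
      " labels:", paste(sprintf("%s=%d", levels(x$class_labels),
                                tabulate(x$class_labels,
                                         nbins = nlevels(x$class_labels))),
                        collapse = " "), "\n")
  invisible(x)
}

#' Subset an epoch set by epoch index
#' @param es an `epoch_set`.
#' @param idx integer or logical index over epochs.
#' @param drop_levels drop unused label levels (default FALSE so the class
#'   encoding stays aligned with the full cohort).
#' @export
subset_epochs <- function(es, idx, drop_levels = FALSE) {
  lab <- es$class_labels[idx]
  if (drop_levels) lab <- droplevels(lab)
  epoch_set(es$epochs[idx, , , drop = FALSE], es$subject_ids[idx], lab,
            es$fs, es$montage, levels = levels(lab))
}

#' Concatenate epoch sets
#' @param sets list of `epoch_set` objects sharing fs and montage.
#' @export
bind_epoch_sets <- function(sets) {
  stopifnot(length(sets) >= 1)
  if (length(sets) == 1) return(sets[[1]])
  fs <- sets[[1]]$fs; mon <- sets[[1]]$montage
  for (s in sets) stopifnot(s$fs == fs, identical(s$montage, mon))
  eps <- do.call(abind3, lapply(sets, function(s) s$epochs))
  labs <- unlist(lapply(sets, function(s) as.character(s$class_labels)))
  epoch_set(eps, unlist(lapply(sets, function(s) s$subject_ids)), labs,
            fs, mon)
}

# bind 3-D arrays along the first dimension
#' @keywords internal
abind3 <- function(...) {
  xs <- list(...)
  d2 <- dim(xs[[1]])[2]; d3 <- dim(xs[[1]])[3]
  n <- sum(vapply(xs, function(x) dim(x)[1], integer(1)))
  out <- array(0, c(n, d2, d3))
  at <- 0L
  for (x in xs) {
    k <- dim(x)[1]
    if (k > 0) out[at + seq_len(k), , ] <- x
    at <- at + k
  }
  out
}
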