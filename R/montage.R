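#' Standard 64-channel 10/20 montage
#'
#' Returns the electrode layout used throughout the package: 64 scalp
#' channels named after the extended 10/20 placement system, in a fixed
#' order, together with schematic 2-D head coordinates for topographic
#' plots. The set contains the midline centro-parietal reference CPz and
#' the posterior/frontal channels most often reported as discriminative in
#' resting-state EEG studies of psychiatric disorders (O1, O2, PO4, P3,
#' P7, P8, Fp1, F8).
#'
#' @return A data.frame with one row per channel and columns `name`
#'   (10/20 label), `index` (0-based position in the data matrix), and
#'   `x`, `y` (schematic coordinates on the unit head disc; the nose
#'   points towards positive `y`).
#' @examples
#' m <- montage_1020()
#' nrow(m)            # 64
#' subset(m, name == "O1")
#' @export
montage_1020 <- function() {
  rows <- list(
    list(y = 0.85, w = 0.38, labels = c("Fp1", "Fpz", "Fp2")),
    list(y = 0.68, w = 0.62, labels = c("AF7", "AF3", "AFz", "AF4", "AF8")),
    list(y = 0.50, w = 0.80, labels = c("F7", "F5", "F3", "F1", "Fz",
                                        "F2", "F4", "F6", "F8")),
    list(y = 0.25, w = 0.93, labels = c("FT7", "FC5", "FC3", "FC1", "FCz",
                                        "FC2", "FC4", "FC6", "FT8")),
    list(y = 0.00, w = 1.00, labels = c("T7", "C5", "C3", "C1", "Cz",
                                        "C2", "C4", "C6", "T8")),
    list(y = -0.25, w = 0.93, labels = c("TP7", "CP5", "CP3", "CP1", "CPz",
                                         "CP2", "CP4", "CP6", "TP8")),
    list(y = -0.50, w = 0.80, labels = c("P7", "P5", "P3", "P1", "Pz",
                                         "P2", "P4", "P6", "P8")),
    list(y = -0.68, w = 0.62, labels = c("PO7", "PO3", "POz", "PO4", "PO8")),
    list(y = -0.85, w = 0.38, labels = c("O1", "Oz", "O2")),
    list(y = -0.72, w = 1.10, labels = c("P9", "Iz", "P10"))
  )
  # Iz sits on the midline below Oz; P9/P10 lateral below P7/P8.
  name <- character(0); x <- numeric(0); y <- numeric(0)
  for (r in rows) {
    k <- length(r$labels)
    xs <- if (k == 1) 0 else seq(-r$w, r$w, length.out = k)
    name <- c(name, r$labels)
    x <- c(x, xs)
    y <- c(y, rep(r$y, k))
  }
  # fix the last irregular row by hand
  iz <- which(name == "Iz"); x[iz] <- 0; y[iz] <- -0.98
  data.frame(name = name, index = seq_along(name) - 1L, x = x, y = y,
             stringsAsFactors = FALSE)
}

#' @keywords internal
check_montage_labels <- function(labels, montage = montage_1020()$name) {
  bad <- setdiff(labels, montage)
  if (length(bad) > 0)
    stop("unknown channel label(s) in signature: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Diagnostic class labels used throughout the package
#' @return Character vector `c("NC", "MDD", "BP", "SZ")`.
#' @export
class_levels <- function() c("NC", "MDD", "BP", "SZ")
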