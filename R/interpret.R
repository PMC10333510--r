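#' Occlusion-based channel importance
#'
#' Measures each channel's discriminative contribution by replacing its row
#' in every epoch with an occluder and recording the mean drop in the
#' model's probability for the true class:
#' `score_c = mean(p_original - p_occluded)`. On z-normalized inputs the
#' `"zeros"` occluder coincides with the channel mean, which is why it is
#' the default.
#'
#' @param model a trained `mcr_model`.
#' @param es an `epoch_set` with true labels; its montage must match the
#'   model's.
#' @param mode `"zeros"` (replace the channel with 0) or `"channel_mean"`
#'   (replace with the channel's per-epoch mean).
#' @return A data.frame of class `mcr_importance` with one row per channel:
#'   `channel`, `score`, `rank` (1 = most important).
#' @export
occlusion_importance <- function(model, es, mode = c("zeros", "channel_mean")) {
  mode <- match.arg(mode)
  if (!identical(es$montage, model$montage))
    stop("montage mismatch between model and epoch set", call. = FALSE)
  stopifnot(n_epochs(es) >= 1)
  y <- match(as.character(es$class_labels), model$classes)
  if (any(is.na(y))) stop("epoch labels outside the model's class set",
                          call. = FALSE)
  n <- n_epochs(es)
  p0 <- predict_probs(model, es)$probs[cbind(seq_len(n), y)]
  nchan <- length(es$montage)
  score <- numeric(nchan)
  for (c in seq_len(nchan)) {
    E2 <- es$epochs
    if (mode == "zeros") {
      E2[, c, ] <- 0
    } else {
      E2[, c, ] <- rowMeans(E2[, c, , drop = FALSE], dims = 2)
    }
    pc <- predict_probs(model, E2)$probs[cbind(seq_len(n), y)]
    score[c] <- mean(p0 - pc)
  }
  out <- data.frame(channel = es$montage, score = score,
                    rank = rank(-score, ties.method = "first"))
  class(out) <- c("mcr_importance", "data.frame")
  out
}

#' Extract penultimate features
#'
#' Returns the 32-dimensional feature vector per epoch used for the
#' low-dimensional disease-spectrum embedding. The default is the
#' time-averaged GRU hidden state entering the fully connected head;
#' `layer = "fc"` returns the FC hidden activations instead.
#'
#' @param model a trained `mcr_model`.
#' @param es an `epoch_set`.
#' @param layer `"gru_avg"` (default) or `"fc"`.
#' @return An `n_epochs x 32` numeric matrix (deterministic: no dropout).
#' @export
extract_penultimate <- function(model, es, layer = c("gru_avg", "fc")) {
  layer <- match.arg(layer)
  f <- predict_probs(model, es)
  if (layer == "gru_avg") f$avg else f$fc_hidden
}

#' Embed features on a 2-D plane
#'
#' Projects the `n x d` penultimate-feature matrix to two dimensions for
#' visualization of the disease spectrum. `method = "umap"` runs the
#' UMAP algorithm (through the umap-learn implementation bundled as a small
#' Python runner; fully seeded) and `method = "pca"` is a fast deterministic
#' principal-component projection.
#'
#' @param features numeric matrix, `n x d`, `n >= 10`.
#' @param seed integer seed for the embedding.
#' @param method `"umap"` or `"pca"`.
#' @param n_neighbors UMAP neighborhood size (default 15); automatically
#'   shrunk with a warning when `n` is too small.
#' @param min_dist UMAP minimum embedding distance (default 0.1).
#' @param subject_ids,class_labels,epoch optional per-row provenance carried
#'   into the result.
#' @return A data.frame of class `mcr_embedding` with columns `dim1`,
#'   `dim2` plus any provenance columns; the seed and method are attached
#'   as attributes.
#' @export
embed_2d <- function(features, seed = 1L, method = c("umap", "pca"),
                     n_neighbors = 15L, min_dist = 0.1,
                     subject_ids = NULL, class_labels = NULL, epoch = NULL) {
  method <- match.arg(method)
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 10) stop("embedding needs at least 10 points", call. = FALSE)
  if (!all(is.finite(features))) stop("non-finite feature values", call. = FALSE)
  if (method == "umap" && n_neighbors >= n) {
    n_neighbors <- max(2L, n - 1L)
    warning("n_neighbors reduced to ", n_neighbors, " for n = ", n)
  }
  if (method == "umap") {
    xy <- run_umap_python(features, seed, n_neighbors, min_dist)
  } else {
    pc <- stats::prcomp(features, center = TRUE, scale. = FALSE)
    xy <- pc$x[, 1:2, drop = FALSE]
    # deterministic sign convention: largest-magnitude loading positive
    for (j in 1:2) {
      l <- pc$rotation[, j]
      if (l[which.max(abs(l))] < 0) xy[, j] <- -xy[, j]
    }
  }
  out <- data.frame(dim1 = xy[, 1], dim2 = xy[, 2])
  if (!is.null(subject_ids)) out$subject_id <- subject_ids
  if (!is.null(class_labels)) out$class_label <- as.character(class_labels)
  if (!is.null(epoch)) out$epoch <- epoch
  attr(out, "seed") <- seed
  attr(out, "method") <- method
  class(out) <- c("mcr_embedding", "data.frame")
  out
}

#' @keywords internal
run_umap_python <- function(features, seed, n_neighbors, min_dist) {
  script <- system.file("python", "umap_embed.py", package = "mcrnn")
  if (script == "") stop("bundled umap_embed.py not found", call. = FALSE)
  fin <- tempfile(fileext = ".csv"); fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  utils::write.table(features, fin, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  res <- suppressWarnings(
    system2("python", c(script, fin, fout, as.integer(seed),
                        as.integer(n_neighbors), format(min_dist)),
            stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if ((!is.null(status) && status != 0) || !file.exists(fout))
    stop("UMAP runner failed: ", paste(utils::tail(res, 3), collapse = " | "),
         call. = FALSE)
  as.matrix(utils::read.table(fout, sep = ","))
}
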