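#' Model specification for the multi-scale convolutional recurrent network
#'
#' Defines the full architecture: parallel 1-D convolution branches over
#' the time axis (each kernel spans all input channels) with exponentially
#' varying kernel lengths, feature concatenation, temporal max-pooling, a
#' gated recurrent unit, time-averaging of the hidden states, and a fully
#' connected softmax head. The defaults give the canonical network for
#' 64-channel, 250-sample (1 s at 250 Hz) epochs: 3 x 32 = 96 concatenated
#' features at 250 timepoints, pooled to 83 timepoints, a 32-unit GRU and a
#' 32-unit hidden layer.
#'
#' @param in_channels number of input channels (default 64).
#' @param in_timepoints samples per epoch (default 250).
#' @param kernel_lengths integer vector of convolution kernel lengths
#'   (default `c(2, 4, 8)`).
#' @param filters_per_scale filters per convolution branch (default 32).
#' @param pool_size temporal max-pooling window and stride (default 3,
#'   non-overlapping).
#' @param gru_hidden GRU hidden-state size (default 32).
#' @param fc_hidden fully connected hidden layer size (default 32).
#' @param n_classes number of output classes (2 or 4 in practice).
#' @param dropout named vector of dropout rates: `conv` (after the
#'   concatenated feature map, default 0.5), `gru` (on GRU inputs, default
#'   0.3), `fc` (after the hidden layer, default 0.5). Active only during
#'   training.
#' @param gru_l1,gru_l2 L1/L2 penalty weights on the GRU input kernel
#'   (defaults 1e-4 each).
#' @return An object of class `mcr_spec`.
#' @examples
#' spec <- model_spec()
#' compute_shapes(spec)
#' @export
model_spec <- function(in_channels = 64L, in_timepoints = 250L,
                       kernel_lengths = c(2L, 4L, 8L),
                       filters_per_scale = 32L, pool_size = 3L,
                       gru_hidden = 32L, fc_hidden = 32L, n_classes = 4L,
                       dropout = c(conv = 0.5, gru = 0.3, fc = 0.5),
                       gru_l1 = 1e-4, gru_l2 = 1e-4) {
  stopifnot(in_channels >= 1, in_timepoints >= 1,
            all(kernel_lengths >= 1), filters_per_scale >= 1,
            pool_size >= 1, gru_hidden >= 1, fc_hidden >= 1, n_classes >= 2)
  dropout <- c(conv = unname(dropout["conv"]), gru = unname(dropout["gru"]),
               fc = unname(dropout["fc"]))
  if (any(is.na(dropout)) || any(dropout < 0) || any(dropout >= 1))
    stop("dropout rates must be named (conv, gru, fc) and lie in [0, 1)",
         call. = FALSE)
  structure(list(in_channels = as.integer(in_channels),
                 in_timepoints = as.integer(in_timepoints),
                 kernel_lengths = as.integer(kernel_lengths),
                 filters_per_scale = as.integer(filters_per_scale),
                 pool_size = as.integer(pool_size),
                 gru_hidden = as.integer(gru_hidden),
                 fc_hidden = as.integer(fc_hidden),
                 n_classes = as.integer(n_classes),
                 dropout = dropout, gru_l1 = gru_l1, gru_l2 = gru_l2),
            class = "mcr_spec")
}

#' @export
print.mcr_spec <- function(x, ...) {
  sh <- compute_shapes(x)
  cat(sprintf("<mcr_spec> %d ch x %d t | conv k=(%s) x %d -> concat (%d, %d) | pool %d -> (%d, %d) | GRU %d | FC %d | %d classes\n",
              x$in_channels, x$in_timepoints,
              paste(x$kernel_lengths, collapse = ","), x$filters_per_scale,
              sh$concat[1], sh$concat[2], x$pool_size,
              sh$pooled[1], sh$pooled[2], x$gru_hidden, x$fc_hidden,
              x$n_classes))
  invisible(x)
}

#' Shapes of every intermediate representation
#'
#' Computes the shape chain implied by a [model_spec()]: each convolution
#' branch preserves the number of timepoints (same-padding), branches are
#' concatenated along the feature axis, and non-overlapping max-pooling
#' truncates `floor(T / pool_size)` windows (trailing remainder dropped).
#'
#' @param spec an `mcr_spec`.
#' @return A list with elements `conv_branch` (per-scale `(timepoints,
#'   filters)`), `concat`, `pooled`, `gru` (each `(timepoints, features)`)
#'   and `logits` (`n_classes`).
#' @export
compute_shapes <- function(spec) {
  stopifnot(inherits(spec, "mcr_spec"))
  if (spec$pool_size > spec$in_timepoints)
    stop(sprintf("invalid spec: pool_size (%d) exceeds in_timepoints (%d)",
                 spec$pool_size, spec$in_timepoints), call. = FALSE)
  t0 <- spec$in_timepoints
  featdim <- spec$filters_per_scale * length(spec$kernel_lengths)
  tp <- t0 %/% spec$pool_size
  list(conv_branch = lapply(spec$kernel_lengths,
                            function(k) c(t0, spec$filters_per_scale)),
       concat = c(t0, featdim),
       pooled = c(tp, featdim),
       gru = c(tp, spec$gru_hidden),
       logits = spec$n_classes)
}

#' Initialize network weights
#'
#' Seeded Glorot-style uniform initialization: each weight matrix is drawn
#' from `U(-a, a)` with `a = sqrt(6 / (fan_in + fan_out))`; biases start at
#' zero. Convolution kernels for length `k` are stored as
#' `(in_channels * k) x filters` matrices with row index
#' `(offset * in_channels + channel)`; the GRU input kernel is
#' `featdim x 3*hidden` with column blocks (update, reset, candidate).
#'
#' @param spec an `mcr_spec`.
#' @param seed integer seed.
#' @return Named parameter list with elements `conv` (one `(W, b)` pair per
#'   kernel length), `gru` (`Wx`, `Wh`, `b`) and `fc1`, `fc2`.
#' @export
init_weights <- function(spec, seed = 1L) {
  set.seed(seed)
  glorot <- function(fin, fout, nr = fin, nc = fout)
    matrix(stats::runif(nr * nc, -1, 1) * sqrt(6 / (fin + fout)), nr, nc)
  C <- spec$in_channels; Fk <- spec$filters_per_scale
  featdim <- Fk * length(spec$kernel_lengths)
  H <- spec$gru_hidden
  conv <- lapply(spec$kernel_lengths, function(k)
    list(W = glorot(C * k, Fk), b = numeric(Fk)))
  names(conv) <- as.character(spec$kernel_lengths)
  list(conv = conv,
       gru = list(Wx = glorot(featdim, H, featdim, 3L * H),
                  Wh = glorot(H, H, H, 3L * H),
                  b = numeric(3L * H)),
       fc1 = list(W = glorot(H, spec$fc_hidden), b = numeric(spec$fc_hidden)),
       fc2 = list(W = glorot(spec$fc_hidden, spec$n_classes),
                  b = numeric(spec$n_classes)))
}
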