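#' Multi-scale 1-D convolution over a single epoch
#'
#' Runs the parallel convolution branches on one `channels x timepoints`
#' epoch and concatenates the branch outputs along the feature axis in the
#' order the branches are given (kernel-length order 2, 4, 8 for the
#' default weights). Each branch convolves along time across all channels
#' with stride 1 and same-padding (the extra pad sample goes on the left
#' for even kernel lengths), then applies ReLU.
#'
#' @param epoch numeric matrix, `channels x timepoints`.
#' @param weights list of branches, each `list(W, b)` with `W` a
#'   `(channels * kernel_length) x filters` matrix (row index
#'   `offset * channels + channel`) and `b` a filter bias vector; e.g.
#'   `init_weights(spec)$conv`.
#' @return A `timepoints x total_filters` feature map.
#' @export
multi_scale_conv <- function(epoch, weights) {
  stopifnot(is.matrix(epoch))
  C <- nrow(epoch); T <- ncol(epoch)
  M <- t(epoch)                      # (T x C) = time-major with B = 1
  klens <- vapply(weights, function(p) {
    if (nrow(p$W) %% C != 0)
      stop(sprintf("kernel matrix has %d rows, not a multiple of %d input channels",
                   nrow(p$W), C), call. = FALSE)
    nrow(p$W) / C
  }, numeric(1))
  conv_forward(M, weights, as.integer(klens), T, 1L)
}

#' Temporal max-pooling
#'
#' Non-overlapping windows of length `pool_size` (stride = `pool_size`)
#' along the time axis, per-feature maximum; trailing samples that do not
#' fill a window are dropped.
#'
#' @param fm `timepoints x features` matrix.
#' @param pool_size window length (default 3).
#' @return A `floor(timepoints / pool_size) x features` matrix.
#' @export
max_pool_time <- function(fm, pool_size = 3) {
  stopifnot(is.matrix(fm))
  pool_forward(fm, nrow(fm), 1L, as.integer(pool_size))$P
}

#' GRU forward pass over a feature sequence
#'
#' Standard gated recurrent unit applied stepwise: update gate
#' `z = sigmoid(x Wxz + h Whz + bz)`, reset gate
#' `r = sigmoid(x Wxr + h Whr + br)`, candidate
#' `n = tanh(x Wxn + (r * h) Whn + bn)` (reset gate applied to the
#' recurrent term before the candidate), and
#' `h' = (1 - z) * h + z * n`.
#'
#' @param seq `timepoints x features` input matrix.
#' @param params list with `Wx` (`features x 3*hidden`), `Wh`
#'   (`hidden x 3*hidden`) and `b` (`3*hidden`), column blocks ordered
#'   (update, reset, candidate); e.g. `init_weights(spec)$gru`.
#' @param h0 initial hidden state (defaults to zeros).
#' @return A `timepoints x hidden` matrix of hidden states, one per step.
#' @export
gru_forward <- function(seq, params, h0 = NULL) {
  stopifnot(is.matrix(seq))
  if (any(!is.finite(seq))) stop("non-finite values in GRU input", call. = FALSE)
  Tn <- nrow(seq)
  H <- nrow(params$Wh)
  if (!is.null(h0) && any(h0 != 0))
    return(gru_forward_ref(seq, params, h0))
  g <- gru_forward_mat(seq, Tn, 1L, params$Wx, params$Wh, params$b)
  t(matrix(g$hs, H, Tn))   # hs has dim (1, H, Tn)
}

# plain-R GRU recurrence for a non-zero initial state
#' @keywords internal
gru_forward_ref <- function(seq, params, h0) {
  H <- nrow(params$Wh)
  iz <- seq_len(H); ir <- H + iz; inn <- 2L * H + iz
  h <- matrix(h0, 1, H)
  out <- matrix(0, nrow(seq), H)
  for (t in seq_len(nrow(seq))) {
    gx <- seq[t, , drop = FALSE] %*% params$Wx + params$b
    rec <- h %*% params$Wh[, c(iz, ir), drop = FALSE]
    z <- sigmoid(gx[, iz] + rec[, iz])
    r <- sigmoid(gx[, ir] + rec[, H + iz])
    n <- tanh(gx[, inn] + (r * h) %*% params$Wh[, inn, drop = FALSE])
    h <- (1 - z) * h + z * n
    out[t, ] <- h
  }
  out
}

#' Classification head
#'
#' Averages the GRU hidden states over time (the 32-dimensional feature
#' exposed for embedding), applies the fully connected hidden layer with
#' ReLU, maps linearly to class logits and applies softmax.
#'
#' @param hidden `timepoints x hidden` matrix of GRU states.
#' @param fc1,fc2 `list(W, b)` parameter pairs for the hidden and output
#'   layers (e.g. `init_weights(spec)$fc1` / `$fc2`).
#' @return A list with `probs` (class probabilities summing to 1), `avg`
#'   (the time-averaged hidden state) and `fc_hidden` (the FC activations).
#' @export
head_forward <- function(hidden, fc1, fc2) {
  stopifnot(is.matrix(hidden))
  avg <- matrix(colMeans(hidden), 1)
  a1 <- relu(add_bias(avg %*% fc1$W, fc1$b))
  logits <- add_bias(a1 %*% fc2$W, fc2$b)
  list(probs = drop(softmax_rows(logits)), avg = drop(avg),
       fc_hidden = drop(a1))
}

#' Forward pass of the full network over an epoch set
#'
#' Evaluation-mode forward pass (no dropout) over all epochs, in chunks.
#'
#' @param model an `mcr_model` (see [fit_mcrnn()]).
#' @param es an `epoch_set` (or a bare `n x channels x timepoints` array).
#' @param chunk maximum epochs per forward chunk (memory control).
#' @return A list with `probs` (`n x n_classes`), `avg` and `fc_hidden`
#'   (`n x hidden` feature matrices).
#' @export
predict_probs <- function(model, es, chunk = 512L) {
  E <- if (inherits(es, "epoch_set")) es$epochs else es
  n <- dim(E)[1]
  K <- model$spec$n_classes
  probs <- matrix(0, n, K)
  avg <- matrix(0, n, model$spec$gru_hidden)
  fc <- matrix(0, n, model$spec$fc_hidden)
  at <- 1L
  while (at <= n) {
    idx <- at:min(at + chunk - 1L, n)
    f <- mcr_forward_batch(model$params, model$spec,
                           E[idx, , , drop = FALSE], training = FALSE)
    probs[idx, ] <- f$probs
    avg[idx, ] <- f$avg
    fc[idx, ] <- f$fc_hidden
    at <- at + length(idx)
  }
  colnames(probs) <- model$classes
  list(probs = probs, avg = avg, fc_hidden = fc)
}
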