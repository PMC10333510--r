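# Vectorised forward/backward engine. The batched path computes the heavy
# kernels in single precision (the deep-learning standard); the exported
# single-epoch operations use the double-precision reference kernels.
#
# Layout conventions (fixed across the package):
#  * a batch of epochs is an array E of dim (B, C, T);
#  * the "time-major" matrix M is (T*B) x C with row r = t + (b-1)*T;
#  * same-padding places the extra pad sample on the LEFT for even kernels
#    (pad_left = ceiling((k-1)/2));
#  * max-pool ties resolve to the earliest sample in the window;
#  * GRU (update gate z, reset gate r, candidate n, reset applied to the
#    recurrent term before the candidate):
#      z = sigmoid(x Wxz + h Whz + bz)
#      r = sigmoid(x Wxr + h Whr + br)
#      n = tanh(x Wxn + (r * h) Whn + bn)
#      h' = (1 - z) * h + z * n

#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

#' @keywords internal
relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' @keywords internal
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# add a bias vector to every row of a matrix
#' @keywords internal
add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

#' @keywords internal
time_major <- function(E) {
  d <- dim(E)  # (B, C, T)
  matrix(aperm(E, c(3, 1, 2)), d[3] * d[1], d[2])
}

# multi-branch convolution + ReLU via a single channel-mix GEMM (compiled)
#' @keywords internal
conv_forward <- function(M, conv_params, kernel_lengths, T, B,
                         single = FALSE) {
  C <- ncol(M)
  slabs <- unlist(lapply(seq_along(kernel_lengths), function(i) {
    W <- conv_params[[i]]$W
    lapply(0:(kernel_lengths[i] - 1), function(j)
      W[j * C + seq_len(C), , drop = FALSE])
  }), recursive = FALSE)
  Wall <- do.call(cbind, slabs)
  ball <- unlist(lapply(conv_params, `[[`, "b"))
  fn <- if (single) cpp_conv_forward_f else cpp_conv_forward
  fn(M, Wall, ball, as.integer(kernel_lengths),
     length(conv_params[[1]]$b), as.integer(T), as.integer(B))
}

# kernel gradients for all branches via one scatter + GEMM (compiled)
#' @keywords internal
conv_backward <- function(M, dH, conv_params, kernel_lengths, T, B,
                          single = FALSE) {
  Fk <- length(conv_params[[1]]$b)
  C <- ncol(M)
  fn <- if (single) cpp_conv_backward_f else cpp_conv_backward
  r <- fn(M, dH, as.integer(kernel_lengths), Fk,
          as.integer(T), as.integer(B))
  out <- vector("list", length(kernel_lengths))
  ucol <- 0L
  for (i in seq_along(kernel_lengths)) {
    k <- kernel_lengths[i]
    dW <- matrix(0, C * k, Fk)
    for (j in 0:(k - 1)) {
      dW[j * C + seq_len(C), ] <- r$dWall[, ucol + seq_len(Fk), drop = FALSE]
      ucol <- ucol + Fk
    }
    out[[i]] <- list(W = dW, b = r$db[(i - 1) * Fk + seq_len(Fk)])
  }
  names(out) <- names(conv_params)
  out
}

# non-overlapping temporal max-pool (compiled); ties keep the earliest
# sample in the window
#' @keywords internal
pool_forward <- function(H, T, B, pool) {
  if (T < pool) stop("invalid input: ", T, " timepoints < pool size ", pool,
                     call. = FALSE)
  cpp_pool_forward(H, as.integer(T), as.integer(B), as.integer(pool))
}

#' @keywords internal
pool_backward <- function(dP, bestp, T, B, pool, featdim) {
  cpp_pool_backward(dP, bestp, as.integer(T), as.integer(B),
                    as.integer(pool), as.integer(featdim))
}

# GRU over a (n_pool*B) x F input (row = t + (b-1)*n_pool); compiled
# recurrence. Gate/state histories come back as (B, H, Tn) arrays plus the
# time-averaged hidden state.
#' @keywords internal
gru_forward_mat <- function(P, Tn, B, Wx, Wh, b, h0 = NULL,
                            single = FALSE) {
  stopifnot(is.null(h0) || all(h0 == 0))  # engine always starts from zeros
  fn <- if (single) cpp_gru_forward_f else cpp_gru_forward
  fn(P, Wx, Wh, b, as.integer(Tn), as.integer(B))
}

#' @keywords internal
gru_backward_mat <- function(P, Tn, B, Wx, Wh, b, g, davg, single = FALSE) {
  if (single)
    cpp_gru_backward_f(P, Wx, Wh, g$hs, g$zs, g$rs, g$ns, davg,
                       as.integer(Tn), as.integer(B))
  else
    cpp_gru_backward(P, Wx, Wh, g$hs, g$zs, g$rs, g$ns, davg,
                     as.integer(Tn), as.integer(B))
}

#' @keywords internal
dropout_mask <- function(nr, nc, rate) {
  if (rate <= 0) return(NULL)
  matrix((stats::runif(nr * nc) >= rate) / (1 - rate), nr, nc)
}

# Full forward pass over a batch array E (B, C, T). In training mode
# dropout masks are drawn from the current RNG stream and kept in the
# cache for the backward pass.
#' @keywords internal
mcr_forward_batch <- function(params, spec, E, training = FALSE,
                              keep_cache = FALSE) {
  d <- dim(E)
  B <- d[1]; T <- d[3]
  stopifnot(d[2] == spec$in_channels, T == spec$in_timepoints)
  M <- time_major(E)
  H <- conv_forward(M, params$conv, spec$kernel_lengths, T, B,
                    single = TRUE)
  Dc <- NULL
  if (training && spec$dropout["conv"] > 0) {
    Dc <- dropout_mask(nrow(H), ncol(H), spec$dropout["conv"])
    H <- H * Dc
  }
  pf <- pool_forward(H, T, B, spec$pool_size)
  P <- pf$P
  Dg <- NULL
  if (training && spec$dropout["gru"] > 0) {
    # one mask per (sample, feature), shared across timesteps
    Dg <- dropout_mask(B, ncol(P), spec$dropout["gru"])
    P <- P * Dg[rep(seq_len(B), each = pf$n_pool), , drop = FALSE]
  }
  g <- gru_forward_mat(P, pf$n_pool, B, params$gru$Wx, params$gru$Wh,
                       params$gru$b, single = TRUE)
  avg <- g$avg
  F1 <- add_bias(avg %*% params$fc1$W, params$fc1$b)
  A1 <- relu(F1)
  A1d <- A1
  Df <- NULL
  if (training && spec$dropout["fc"] > 0) {
    Df <- dropout_mask(nrow(A1), ncol(A1), spec$dropout["fc"])
    A1d <- A1 * Df
  }
  logits <- add_bias(A1d %*% params$fc2$W, params$fc2$b)
  probs <- softmax_rows(logits)
  out <- list(probs = probs, logits = logits, avg = avg, fc_hidden = A1)
  if (keep_cache)
    out$cache <- list(M = M, T = T, B = B, relu_conv = NULL, Dc = Dc,
                      pf = pf, P = P, Dg = Dg, g = g, avg = avg,
                      F1 = F1, A1 = A1, A1d = A1d, Df = Df, H = H)
  out
}

# Backward pass; y is an integer class vector (1-based), weights an optional
# per-sample weight vector (mean-normalised by the caller).
#' @keywords internal
mcr_backward_batch <- function(params, spec, fwd, y, sample_w = NULL) {
  cache <- fwd$cache
  B <- cache$B; T <- cache$T
  K <- spec$n_classes
  probs <- fwd$probs
  Y <- matrix(0, B, K); Y[cbind(seq_len(B), y)] <- 1
  w <- if (is.null(sample_w)) rep(1, B) else sample_w
  dlogits <- (probs - Y) * (w / B)
  dW2 <- crossprod(cache$A1d, dlogits)
  db2 <- colSums(dlogits)
  dA1d <- dlogits %*% t(params$fc2$W)
  dA1 <- if (is.null(cache$Df)) dA1d else dA1d * cache$Df
  dF1 <- dA1 * (cache$F1 > 0)
  dW1 <- crossprod(cache$avg, dF1)
  db1 <- colSums(dF1)
  davg <- dF1 %*% t(params$fc1$W)
  gb <- gru_backward_mat(cache$P, cache$pf$n_pool, B, params$gru$Wx,
                         params$gru$Wh, params$gru$b, cache$g, davg,
                         single = TRUE)
  dP <- gb$dP
  if (!is.null(cache$Dg))
    dP <- dP * cache$Dg[rep(seq_len(B), each = cache$pf$n_pool), , drop = FALSE]
  featdim <- ncol(cache$H)
  dH <- pool_backward(dP, cache$pf$bestp, T, B, spec$pool_size, featdim)
  if (!is.null(cache$Dc)) dH <- dH * cache$Dc
  # ReLU subgradient: pre-activation > 0 <=> post-ReLU value > 0. The cached
  # H is post-dropout, but cells zeroed by dropout already have zero gradient
  # after the Dc product above, so (H != 0) is an equivalent mask.
  Hmask <- if (is.null(cache$Dc)) cache$H > 0 else cache$H != 0
  dH <- dH * Hmask
  conv_grads <- conv_backward(cache$M, dH, params$conv, spec$kernel_lengths,
                              T, B, single = TRUE)
  # regularization on the GRU input kernel
  dWx <- gb$dWx + spec$gru_l1 * sign(params$gru$Wx) +
         2 * spec$gru_l2 * params$gru$Wx
  nll <- -sum(w * log(pmax(probs[cbind(seq_len(B), y)], 1e-12))) / B
  reg <- spec$gru_l1 * sum(abs(params$gru$Wx)) +
         spec$gru_l2 * sum(params$gru$Wx^2)
  list(grads = list(conv = conv_grads,
                    gru = list(Wx = dWx, Wh = gb$dWh, b = gb$db),
                    fc1 = list(W = dW1, b = db1),
                    fc2 = list(W = dW2, b = db2)),
       loss = nll + reg, nll = nll)
}
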