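# Brute-force reference implementations, written as plain nested loops and
# kept deliberately independent of the package's vectorised/compiled path.

oracle_conv <- function(epoch, W, b) {
  C <- nrow(epoch); T <- ncol(epoch)
  k <- nrow(W) / C
  F <- length(b)
  pad_left <- ceiling((k - 1) / 2)
  out <- matrix(0, T, F)
  for (t in seq_len(T)) {
    for (f in seq_len(F)) {
      acc <- b[f]
      for (j in 0:(k - 1)) {
        src <- t - pad_left + j
        if (src >= 1 && src <= T) {
          for (c in seq_len(C)) acc <- acc + epoch[c, src] * W[j * C + c, f]
        }
      }
      out[t, f] <- max(acc, 0)
    }
  }
  out
}

oracle_pool <- function(fm, pool) {
  n <- floor(nrow(fm) / pool)
  out <- matrix(0, n, ncol(fm))
  for (w in seq_len(n)) {
    for (f in seq_len(ncol(fm))) {
      out[w, f] <- max(fm[(w - 1) * pool + seq_len(pool), f])
    }
  }
  out
}

oracle_gru <- function(seq, Wx, Wh, b, h0 = NULL) {
  H <- nrow(Wh)
  sig <- function(x) 1 / (1 + exp(-x))
  h <- if (is.null(h0)) rep(0, H) else h0
  out <- matrix(0, nrow(seq), H)
  for (t in seq_len(nrow(seq))) {
    x <- seq[t, ]
    a <- drop(x %*% Wx) + b + c(drop(h %*% Wh[, 1:(2 * H)]), rep(0, H))
    z <- sig(a[1:H])
    r <- sig(a[H + 1:H])
    n <- tanh(a[2 * H + 1:H] + drop((r * h) %*% Wh[, 2 * H + 1:H]))
    h <- (1 - z) * h + z * n
    out[t, ] <- h
  }
  out
}

# tiny random GRU parameter set
random_gru_params <- function(Fin, H) {
  list(Wx = matrix(rnorm(Fin * 3 * H, sd = 0.5), Fin, 3 * H),
       Wh = matrix(rnorm(H * 3 * H, sd = 0.5), H, 3 * H),
       b = rnorm(3 * H, sd = 0.2))
}
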