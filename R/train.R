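#' Training configuration
#'
#' The optimization regime: Adam on the cross-entropy loss plus the GRU
#' kernel L1/L2 penalty, batch size 512, learning rate 0.001 with
#' inverse-time decay (rate 0.01 per epoch), early stopping when the
#' validation loss has not reached a new minimum for `patience` consecutive
#' epochs (or at `max_epochs`), and model selection by the highest
#' validation accuracy seen during the run.
#'
#' @param batch_size minibatch size (default 512).
#' @param lr0 initial learning rate (default 0.001).
#' @param decay decay rate per epoch (default 0.01).
#' @param decay_mode `"inverse_time"` (`lr0 / (1 + decay * epoch)`, the
#'   classic framework semantics, default) or `"multiplicative"`
#'   (`lr0 * (1 - decay)^epoch`).
#' @param max_epochs maximum training epochs (default 1000).
#' @param patience early-stopping patience in epochs (default 50).
#' @param val_fraction fraction of the training samples held out for
#'   validation (default 0.2).
#' @param val_split_level `"epoch"` (sample 20% of epochs uniformly — the
#'   literal regime, which can share a subject across the split) or
#'   `"subject"` (hold out whole subjects). Epoch-level splitting of
#'   same-subject epochs inflates validation scores; a warning is logged
#'   once per fit.
#' @param class_weights `"none"` (default) or `"inverse_frequency"` for
#'   imbalanced cohorts.
#' @param seed integer seed controlling the split, initialization, shuffling
#'   and dropout.
#' @return An object of class `mcr_train_spec`.
#' @export
train_spec <- function(batch_size = 512L, lr0 = 0.001, decay = 0.01,
                       decay_mode = c("inverse_time", "multiplicative"),
                       max_epochs = 1000L, patience = 50L,
                       val_fraction = 0.2,
                       val_split_level = c("epoch", "subject"),
                       class_weights = c("none", "inverse_frequency"),
                       seed = 1L) {
  stopifnot(val_fraction > 0, val_fraction < 1, patience < max_epochs,
            batch_size >= 1, lr0 > 0, decay >= 0)
  structure(list(batch_size = as.integer(batch_size), lr0 = lr0,
                 decay = decay, decay_mode = match.arg(decay_mode),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction,
                 val_split_level = match.arg(val_split_level),
                 class_weights = match.arg(class_weights),
                 seed = as.integer(seed)),
            class = "mcr_train_spec")
}

#' Learning-rate schedule
#'
#' Inverse-time decay `lr0 / (1 + decay * epoch)` (monotone non-increasing;
#' epoch counted from 0), or multiplicative decay when the training spec
#' says so.
#'
#' @param epoch 0-based epoch index.
#' @param tspec an `mcr_train_spec`.
#' @return The learning rate for that epoch.
#' @examples
#' lr_schedule(0, train_spec())    # 0.001
#' lr_schedule(100, train_spec())  # 0.0005
#' @export
lr_schedule <- function(epoch, tspec) {
  stopifnot(epoch >= 0)
  if (tspec$decay_mode == "inverse_time")
    tspec$lr0 / (1 + tspec$decay * epoch)
  else
    tspec$lr0 * (1 - tspec$decay)^epoch
}

#' Split an epoch set into training and validation parts
#'
#' Epoch-level mode samples `val_fraction` of the epochs uniformly at
#' random; subject-level mode holds out whole subjects (retrying up to 100
#' stratification draws so that every class appears on both sides). The two
#' sides are always disjoint.
#'
#' @param es an `epoch_set`.
#' @param tspec an `mcr_train_spec` (supplies fraction, level and seed).
#' @return `list(train = epoch_set, val = epoch_set)`.
#' @export
split_validation <- function(es, tspec) {
  n <- n_epochs(es)
  stopifnot(n > 1)
  set.seed(tspec$seed)
  if (tspec$val_split_level == "epoch") {
    n_val <- max(1L, round(n * tspec$val_fraction))
    val_idx <- sort(sample.int(n, n_val))
  } else {
    subj <- unique(es$subject_ids)
    n_val_s <- max(1L, round(length(subj) * tspec$val_fraction))
    ok <- FALSE
    for (try in seq_len(100)) {
      vs <- sample(subj, n_val_s)
      val_idx <- which(es$subject_ids %in% vs)
      lv <- unique(es$class_labels[val_idx])
      lt <- unique(es$class_labels[-val_idx])
      if (setequal(lv, levels(droplevels(es$class_labels))) &&
          setequal(lt, levels(droplevels(es$class_labels)))) { ok <- TRUE; break }
    }
    if (!ok) stop("could not stratify a subject-level validation split after 100 attempts",
                  call. = FALSE)
    val_idx <- sort(val_idx)
  }
  list(train = subset_epochs(es, setdiff(seq_len(n), val_idx)),
       val = subset_epochs(es, val_idx))
}

# one Adam step over the nested parameter list
#' @keywords internal
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else upd(p, g, m, v)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(t = state$t, m = r$m, v = r$v))
}

#' @keywords internal
zeros_like <- function(p) {
  if (is.list(p)) lapply(p, zeros_like) else p * 0
}

#' @keywords internal
eval_loss_acc <- function(params, spec, E, y, chunk = 512L) {
  n <- dim(E)[1]
  nll <- 0; correct <- 0
  at <- 1L
  while (at <= n) {
    idx <- at:min(at + chunk - 1L, n)
    f <- mcr_forward_batch(params, spec, E[idx, , , drop = FALSE])
    p <- f$probs
    nll <- nll - sum(log(pmax(p[cbind(seq_along(idx), y[idx])], 1e-12)))
    correct <- correct + sum(max.col(p, ties.method = "first") == y[idx])
    at <- at + length(idx)
  }
  reg <- spec$gru_l1 * sum(abs(params$gru$Wx)) + spec$gru_l2 * sum(params$gru$Wx^2)
  list(loss = nll / n + reg, acc = correct / n)
}

#' Train the network
#'
#' Minimizes cross-entropy (plus the L1/L2 GRU-kernel penalty) with Adam
#' under the regime in `tspec`: shuffled minibatches, per-epoch learning
#' rate from [lr_schedule()], dropout active, early stopping on the
#' validation loss, and selection of the weights with the highest
#' validation accuracy. Fully reproducible for a fixed `tspec$seed`.
#'
#' @param train,val `epoch_set`s (e.g. from [split_validation()]); their
#'   label levels define the class encoding.
#' @param mspec an `mcr_spec`; `n_classes` must match the label levels.
#' @param tspec an `mcr_train_spec`.
#' @param verbose print a line per epoch.
#' @return An object of class `mcr_fit`: `model` (an `mcr_model` carrying
#'   the best-validation-accuracy weights), `history` (per-epoch
#'   data.frame: epoch, lr, train_loss, val_loss, val_acc), `best_epoch`,
#'   `stopped_epoch` and `reason` (`"patience"` or `"max_epochs"`).
#' @export
fit_mcrnn <- function(train, val, mspec, tspec, verbose = FALSE) {
  lev <- levels(train$class_labels)
  if (length(lev) != mspec$n_classes)
    stop(sprintf("label set has %d levels but the model expects %d classes",
                 length(lev), mspec$n_classes), call. = FALSE)
  Etr <- train$epochs; ytr <- as.integer(train$class_labels)
  Eva <- val$epochs;   yva <- as.integer(val$class_labels)
  n <- dim(Etr)[1]
  set.seed(tspec$seed)
  params <- init_weights(mspec, seed = tspec$seed)
  state <- list(t = 0L, m = zeros_like(params), v = zeros_like(params))
  sample_w <- NULL
  if (tspec$class_weights == "inverse_frequency") {
    freq <- tabulate(ytr, nbins = mspec$n_classes)
    wcl <- ifelse(freq > 0, 1 / freq, 0)
    wcl <- wcl * length(ytr) / sum(wcl * freq)  # mean weight 1
    sample_w <- wcl[ytr]
  }
  history <- data.frame(epoch = integer(0), lr = numeric(0),
                        train_loss = numeric(0), val_loss = numeric(0),
                        val_acc = numeric(0))
  best_val_loss <- Inf; best_val_acc <- -Inf
  best_params <- params; best_epoch <- 0L
  since_improve <- 0L; reason <- "max_epochs"; epoch <- 0L
  for (epoch in seq_len(tspec$max_epochs)) {
    lr <- lr_schedule(epoch - 1L, tspec)
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    at <- 1L
    while (at <= n) {
      idx <- ord[at:min(at + tspec$batch_size - 1L, n)]
      fwd <- mcr_forward_batch(params, mspec, Etr[idx, , , drop = FALSE],
                               training = TRUE, keep_cache = TRUE)
      bwd <- mcr_backward_batch(params, mspec, fwd, ytr[idx],
                                sample_w = sample_w[idx])
      if (!is.finite(bwd$loss))
        stop(sprintf("training diverged (non-finite loss) at epoch %d, lr %g",
                     epoch, lr), call. = FALSE)
      st <- adam_step(params, bwd$grads, state, lr)
      params <- st$params; state <- st$state
      ep_loss <- ep_loss + bwd$loss; nb <- nb + 1L
      at <- at + tspec$batch_size
    }
    ev <- eval_loss_acc(params, mspec, Eva, yva)
    history <- rbind(history, data.frame(epoch = epoch, lr = lr,
                                         train_loss = ep_loss / nb,
                                         val_loss = ev$loss,
                                         val_acc = ev$acc))
    if (verbose)
      message(sprintf("epoch %3d lr %.5f train %.4f val %.4f acc %.3f",
                      epoch, lr, ep_loss / nb, ev$loss, ev$acc))
    if (ev$acc > best_val_acc) {
      best_val_acc <- ev$acc
      best_params <- params
      best_epoch <- epoch
    }
    # improvements below 1e-6 are within single-precision forward jitter
    # and do not reset the patience counter
    if (ev$loss < best_val_loss - 1e-6) {
      best_val_loss <- ev$loss
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= tspec$patience) { reason <- "patience"; break }
    }
  }
  model <- structure(list(spec = mspec, params = best_params, classes = lev,
                          montage = train$montage),
                     class = "mcr_model")
  structure(list(model = model, history = history, best_epoch = best_epoch,
                 stopped_epoch = epoch, reason = reason,
                 final_params = params),
            class = "mcr_fit")
}

#' @export
print.mcr_fit <- function(x, ...) {
  cat(sprintf("<mcr_fit> stopped at epoch %d (%s); best val acc %.3f at epoch %d\n",
              x$stopped_epoch, x$reason,
              max(x$history$val_acc), x$best_epoch))
  invisible(x)
}

#' @export
print.mcr_model <- function(x, ...) {
  cat(sprintf("<mcr_model> %d-class network over %d channels (%s)\n",
              x$spec$n_classes, x$spec$in_channels,
              paste(x$classes, collapse = "/")))
  invisible(x)
}

#' Predict class labels for an epoch set
#' @param object an `mcr_model`.
#' @param es an `epoch_set`.
#' @param ... unused.
#' @return Factor of per-epoch predicted labels.
#' @export
predict.mcr_model <- function(object, es, ...) {
  p <- predict_probs(object, es)$probs
  factor(object$classes[max.col(p, ties.method = "first")],
         levels = object$classes)
}
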