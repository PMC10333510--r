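#' Aggregate per-epoch probabilities into one subject-level prediction
#'
#' Arithmetic mean of the per-epoch probability vectors, then argmax.
#' Exact ties resolve to the lowest class index.
#'
#' @param probs `n_epochs x n_classes` matrix of probabilities (>= 1 row).
#' @return Integer index of the predicted class (1-based); the mean
#'   probability vector is attached as attribute `"mean_probs"`.
#' @export
aggregate_subject <- function(probs) {
  probs <- rbind(probs)
  if (nrow(probs) == 0) stop("no epochs to aggregate", call. = FALSE)
  m <- colMeans(probs)
  pred <- which.max(m)   # which.max returns the first (lowest) index on ties
  attr(pred, "mean_probs") <- m
  pred
}

#' Subject-level leave-one-out cross-validation
#'
#' One fold per subject: fold `k` trains on every other subject's epochs
#' (with the validation split drawn inside the fold's training data) and
#' predicts all epochs of the held-out subject. Per-fold seeds are derived
#' from `tspec$seed` so the whole evaluation is reproducible. Each fold
#' asserts the no-leakage invariant: none of the held-out subject's epochs
#' may appear in the fold's training or validation sets.
#'
#' @param es the cohort `epoch_set`.
#' @param mspec an `mcr_spec` (its `n_classes` must match the label levels
#'   present in `es`).
#' @param tspec an `mcr_train_spec`.
#' @param verbose print one line per fold.
#' @return A list of fold results, each with `subject`, `true` (label),
#'   `probs` (per-epoch probability matrix), `pred` (subject-level
#'   predicted label), `epoch_preds`, `train_subjects` and `n_train_epochs`.
#' @export
loocv <- function(es, mspec, tspec, verbose = FALSE) {
  lev <- levels(droplevels(es$class_labels))
  if (length(lev) < 2) stop("leave-one-out needs at least two classes",
                            call. = FALSE)
  subjects <- unique(es$subject_ids)
  folds <- vector("list", length(subjects))
  for (k in seq_along(subjects)) {
    s <- subjects[k]
    test_idx <- which(es$subject_ids == s)
    rest_idx <- setdiff(seq_len(n_epochs(es)), test_idx)
    rest <- subset_epochs(es, rest_idx)
    rest$class_labels <- factor(as.character(rest$class_labels), levels = lev)
    fold_tspec <- tspec
    fold_tspec$seed <- as.integer(tspec$seed + 101L * k)
    sp <- split_validation(rest, fold_tspec)
    # no-leakage audit
    if (s %in% sp$train$subject_ids || s %in% sp$val$subject_ids)
      stop("leakage: held-out subject found in fold training data")
    fit <- fit_mcrnn(sp$train, sp$val, mspec, fold_tspec)
    test <- subset_epochs(es, test_idx)
    probs <- predict_probs(fit$model, test)$probs
    pred_i <- aggregate_subject(probs)
    folds[[k]] <- list(subject = s,
                       true = as.character(es$class_labels[test_idx[1]]),
                       probs = probs,
                       pred = lev[pred_i],
                       epoch_preds = lev[max.col(probs, ties.method = "first")],
                       train_subjects = unique(rest$subject_ids),
                       n_train_epochs = n_epochs(sp$train),
                       test_idx = test_idx,
                       trainval_idx = rest_idx,
                       best_epoch = fit$best_epoch)
    if (verbose)
      message(sprintf("fold %2d/%d subject %s: true %s pred %s",
                      k, length(subjects), s, folds[[k]]$true, folds[[k]]$pred))
  }
  structure(folds, class = "mcr_folds", levels = lev)
}

#' Confusion matrix from leave-one-out folds
#'
#' Tallies subject-level predictions into an `n_classes x n_classes` count
#' matrix (rows = true class, columns = predicted class) and derives the
#' overall accuracy and per-class recall. Per-epoch accuracy (labelled as
#' such) is reported alongside, since epoch- and subject-level figures can
#' differ substantially.
#'
#' @param folds result of [loocv()].
#' @return An object of class `mcr_confusion`: `table` (counts), `accuracy`
#'   (subject-level, trace/sum), `recall` (per class), `epoch_accuracy`.
#' @export
confusion <- function(folds) {
  lev <- attr(folds, "levels")
  true <- factor(vapply(folds, `[[`, "", "true"), levels = lev)
  pred <- factor(vapply(folds, `[[`, "", "pred"), levels = lev)
  tab <- table(true = true, predicted = pred)
  ep_true <- unlist(lapply(folds, function(f) rep(f$true, nrow(f$probs))))
  ep_pred <- unlist(lapply(folds, function(f) f$epoch_preds))
  structure(list(table = tab,
                 accuracy = sum(diag(tab)) / sum(tab),
                 recall = diag(tab) / pmax(rowSums(tab), 1),
                 epoch_accuracy = mean(ep_true == ep_pred),
                 n_subjects = length(folds)),
            class = "mcr_confusion")
}

#' @export
print.mcr_confusion <- function(x, ...) {
  cat(sprintf("<mcr_confusion> %d subjects, accuracy %.3f (epoch-level %.3f)\n",
              x$n_subjects, x$accuracy, x$epoch_accuracy))
  print(x$table)
  invisible(x)
}
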