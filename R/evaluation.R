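# Confusion-matrix metrics, tie-aware ROC/AUC, stratified k-fold
# cross-validation and the window-size sweep.

#' Build a confusion matrix
#'
#' Either supply the four counts directly, or `truth` and `predicted`
#' label vectors (`"active"` is the positive class).
#'
#' @param tp,fp,fn,tn non-negative counts.
#' @param truth,predicted character vectors of `"active"`/`"inactive"`.
#' @return A list of class `deamid_confusion`.
#' @examples
#' confusion_matrix(tp = 28, fp = 6, fn = 8, tn = 270)
#' @export
confusion_matrix <- function(tp = NULL, fp = NULL, fn = NULL, tn = NULL,
                             truth = NULL, predicted = NULL) {
  if (!is.null(truth)) {
    assert_that(length(truth) == length(predicted),
                "truth/predicted length mismatch",
                class = "deamid_validation_error")
    tp <- sum(truth == "active" & predicted == "active")
    fp <- sum(truth == "inactive" & predicted == "active")
    fn <- sum(truth == "active" & predicted == "inactive")
    tn <- sum(truth == "inactive" & predicted == "inactive")
  }
  cm <- list(tp = as.numeric(tp), fp = as.numeric(fp),
             fn = as.numeric(fn), tn = as.numeric(tn))
  assert_that(all(unlist(cm) >= 0), "counts must be non-negative",
              class = "deamid_validation_error")
  structure(cm, class = "deamid_confusion")
}

#' Compute the six classification metrics from a confusion matrix
#'
#' Accuracy, precision, recall (sensitivity), specificity, F1 and the
#' Matthews correlation coefficient. Any metric whose denominator is zero
#' is reported as 0, keeping aggregation total on degenerate folds.
#'
#' @param cm a [confusion_matrix()] (total count must be positive).
#' @return A list of class `deamid_metrics`.
#' @examples
#' compute_metrics(confusion_matrix(tp = 28, fp = 6, fn = 8, tn = 270))
#' @export
compute_metrics <- function(cm) {
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  total <- tp + fp + fn + tn
  assert_that(total > 0, "empty confusion matrix",
              class = "deamid_validation_error")
  safe <- function(num, den) if (den > 0) num / den else 0
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  structure(list(
    accuracy = (tp + tn) / total,
    precision = safe(tp, tp + fp),
    recall = safe(tp, tp + fn),
    specificity = safe(tn, tn + fp),
    f1 = safe(2 * tp, 2 * tp + fp + fn),
    mcc = if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else 0
  ), class = "deamid_metrics")
}

#' @export
print.deamid_metrics <- function(x, ...) {
  cat(sprintf(paste0("accuracy %.3f  precision %.3f  recall %.3f  ",
                     "specificity %.3f  F1 %.3f  MCC %.3f\n"),
              x$accuracy, x$precision, x$recall, x$specificity, x$f1, x$mcc))
  invisible(x)
}

#' Area under the ROC curve (rank statistic)
#'
#' Computed as the probability that a uniformly chosen active site outscores
#' a uniformly chosen inactive one, with ties counting one half -- the exact
#' Mann-Whitney formulation, equivalent to trapezoidal ROC integration over
#' all thresholds.
#'
#' @param scores numeric scores (higher = more likely active).
#' @param labels `"active"`/`"inactive"` per score.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == "active"
  n1 <- sum(pos); n0 <- sum(!pos)
  assert_that(n1 > 0 && n0 > 0, "both classes required for ROC",
              class = "deamid_validation_error")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @param scores,labels as in [roc_auc()].
#' @return A data frame of (fpr, tpr) pairs over all score thresholds,
#'   suitable for plotting or CSV export.
#' @export
roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  pos <- labels[ord] == "active"
  tpr <- cumsum(pos) / sum(pos)
  fpr <- cumsum(!pos) / sum(!pos)
  keep <- !duplicated(scores[ord], fromLast = TRUE)
  data.frame(fpr = c(0, fpr[keep]), tpr = c(0, tpr[keep]))
}

#' Stratified k-fold partition
#'
#' Sites are canonically ordered by (molecule, chain, position) before the
#' seeded shuffle, so fold membership is independent of input row order.
#' Within each class, shuffled members are dealt round-robin, keeping every
#' fold's active fraction within one site of the global fraction.
#'
#' @param labeled labeled data frame with a `label` column.
#' @param k number of folds (>= 2; each class must have >= k members).
#' @param seed integer seed.
#' @return A list of `k` integer vectors of row indices (disjoint, covering
#'   all rows).
#' @export
stratified_kfold <- function(labeled, k, seed = 1L) {
  assert_that(k >= 2, "k must be >= 2", class = "deamid_validation_error")
  cls <- split(seq_len(nrow(labeled)), labeled$label)
  small <- names(cls)[vapply(cls, length, 0L) < k]
  assert_that(length(small) == 0, "class smaller than k: ",
              paste(small, collapse = ", "),
              class = "deamid_validation_error")
  ord <- order(labeled$molecule_id %||% seq_len(nrow(labeled)),
               labeled$chain_id %||% 0, labeled$position %||% 0)
  folds <- vector("list", k)
  sizes <- integer(k)
  with_seed(seed, {
    for (ix in cls) {
      ix <- ix[order(match(ix, ord))]  # canonical order within class
      ix <- ix[sample.int(length(ix))]
      # deal into the currently smallest folds first, so fold totals stay
      # within one site of each other across classes
      deal <- rep_len(order(sizes, seq_len(k)), length(ix))
      for (j in seq_len(k)) folds[[j]] <- c(folds[[j]], ix[deal == j])
      sizes <- vapply(folds, length, 0L)
    }
  })
  lapply(folds, sort)
}

#' Stratified k-fold cross-validation of a model variant
#'
#' For each fold, the model trains on the other k-1 folds (with an inner
#' stratified validation split for early stopping) and is evaluated on the
#' held-out fold. Aggregates are the arithmetic mean and sample (n-1)
#' standard deviation across folds.
#'
#' @param chains chain data frame.
#' @param labeled labeled dataset.
#' @param variant model variant (see [build_model()]).
#' @param config a [run_config()].
#' @param k number of folds (default 5).
#' @param embedder backend for global features (defaults to the one named
#'   in `config`).
#' @param task `"classification"` (default) or `"regression"`.
#' @return A list of class `deamid_cv`: `per_fold` (data frame of metrics
#'   plus AUC per fold), `mean`, `sd`.
#' @export
cross_validate <- function(chains, labeled, variant = "chimeric",
                           config = run_config(), k = 5L, embedder = NULL,
                           task = "classification") {
  if (is.null(embedder) && variant != "local_only") {
    embedder <- embedder_from_name(config$embedder_name)
  }
  features <- featurize_sites(
    chains, labeled,
    embedder = if (variant != "local_only") embedder,
    window_size = if (variant != "global_only") config$window_size)
  folds <- stratified_kfold(labeled, k, config$seed)
  per_fold <- lapply(seq_len(k), function(j) {
    test_ix <- folds[[j]]
    pool_ix <- sort(unlist(folds[-j]))
    pool <- labeled[pool_ix, ]
    inner <- val_split(pool, config$val_fraction, config$seed + j)
    cfgj <- config
    cfgj$seed <- config$seed + j
    model <- build_model(variant, task, cfgj,
                         d = if (variant == "local_only") NULL else embedder$d)
    model <- train_model(model,
                         subset_features(features, pool_ix[inner$train]),
                         pool[inner$train, ],
                         subset_features(features, pool_ix[inner$val]),
                         pool[inner$val, ])
    pred <- predict(model, subset_features(features, test_ix))
    truth <- labeled$label[test_ix]
    m <- compute_metrics(confusion_matrix(truth = truth,
                                          predicted = pred$predicted_label))
    c(fold = j, unlist(m), auc = roc_auc(pred$probability, truth))
  })
  per_fold <- as.data.frame(do.call(rbind, per_fold))
  metric_cols <- setdiff(names(per_fold), "fold")
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold[metric_cols]),
                 sd = vapply(per_fold[metric_cols], sd, 0)),
            class = "deamid_cv")
}

#' @export
print.deamid_cv <- function(x, ...) {
  cat("cross-validation over", nrow(x$per_fold), "folds (mean +/- sd):\n")
  for (m in names(x$mean)) {
    cat(sprintf("  %-12s %.3f +/- %.3f\n", m, x$mean[[m]], x$sd[[m]]))
  }
  invisible(x)
}

#' Window-size sweep for the local sequence model
#'
#' Cross-validates the `local_only` variant at each window size and reports
#' mean cross-validated MCC per size; the optimal size is the argmax.
#'
#' @param chains chain data frame.
#' @param labeled labeled dataset.
#' @param sizes odd window sizes in `[3, 61]`.
#' @param config a [run_config()] (its `window_size` is overridden).
#' @param k folds per size.
#' @return A data frame `(window_size, mcc, accuracy, f1)` with attribute
#'   `best` (the window size of maximal MCC).
#' @export
window_sweep <- function(chains, labeled, sizes = seq(3L, 61L, by = 2L),
                         config = run_config(), k = 5L) {
  assert_that(all(sizes %% 2 == 1 & sizes >= 3 & sizes <= 61),
              "sizes must be odd and within [3, 61]",
              class = "deamid_validation_error")
  rows <- lapply(sizes, function(wsz) {
    cfg <- config
    cfg$window_size <- as.integer(wsz)
    cv <- cross_validate(chains, labeled, "local_only", cfg, k = k)
    data.frame(window_size = wsz, mcc = cv$mean[["mcc"]],
               accuracy = cv$mean[["accuracy"]], f1 = cv$mean[["f1"]])
  })
  out <- do.call(rbind, rows)
  attr(out, "best") <- out$window_size[which.max(out$mcc)]
  out
}
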