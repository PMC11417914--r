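test_that("compute_metrics handles degenerate and perfect inputs", {
  perfect <- compute_metrics(confusion_matrix(tp = 5, fp = 0, fn = 0, tn = 5))
  expect_equal(unclass(perfect)[c("accuracy", "precision", "recall",
                                  "specificity", "f1", "mcc")],
               list(accuracy = 1, precision = 1, recall = 1,
                    specificity = 1, f1 = 1, mcc = 1))
  # zero-denominator metrics are 0 by convention
  none_called <- compute_metrics(confusion_matrix(tp = 0, fp = 0, fn = 3, tn = 7))
  expect_equal(none_called$precision, 0)
  expect_equal(none_called$mcc, 0)
  expect_error(compute_metrics(confusion_matrix(tp = 0, fp = 0, fn = 0, tn = 0)),
               class = "deamid_validation_error")
  expect_error(confusion_matrix(tp = -1, fp = 0, fn = 0, tn = 1),
               class = "deamid_validation_error")
})

test_that("compute_metrics agrees with independent formulas on random matrices", {
  # independent oracle: textbook formulas written directly
  oracle <- function(tp, fp, fn, tn) {
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    den <- as.numeric((tp + fp)) * (tp + fn) * (tn + fp) * (tn + fn)
    list(accuracy = (tp + tn) / (tp + fp + fn + tn),
         precision = prec,
         recall = rec,
         specificity = if (tn + fp > 0) tn / (tn + fp) else 0,
         f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0,
         mcc = if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0)
  }
  set.seed(42)
  for (i in 1:1000) {
    counts <- rpois(4, lambda = sample(c(1, 10, 200), 1))
    if (sum(counts) == 0) counts[1] <- 1
    got <- compute_metrics(confusion_matrix(counts[1], counts[2],
                                            counts[3], counts[4]))
    expect_equal(unclass(got), oracle(counts[1], counts[2], counts[3],
                                      counts[4]),
                 tolerance = 1e-12)
  }
})

test_that("MCC is invariant under class swap", {
  set.seed(9)
  for (i in 1:100) {
    c4 <- rpois(4, 20) + 1
    m1 <- compute_metrics(confusion_matrix(c4[1], c4[2], c4[3], c4[4]))$mcc
    m2 <- compute_metrics(confusion_matrix(c4[4], c4[3], c4[2], c4[1]))$mcc
    expect_equal(m1, m2, tolerance = 1e-12)
  }
})

test_that("roc_auc matches the exhaustive pair-counting oracle", {
  pair_oracle <- function(scores, labels) {
    a <- scores[labels == "active"]; b <- scores[labels == "inactive"]
    pairs <- expand.grid(a = a, b = b)
    mean((pairs$a > pairs$b) + 0.5 * (pairs$a == pairs$b))
  }
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1),
                       c("active", "active", "inactive", "inactive")), 1)
  expect_equal(roc_auc(rep(0.5, 6), rep(c("active", "inactive"), 3)), 0.5)
  set.seed(7)
  for (i in 1:50) {
    n <- sample(4:20, 1)
    labels <- sample(c("active", "inactive"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    expect_equal(roc_auc(scores, labels), pair_oracle(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, rep("active", 3)),
               class = "deamid_validation_error")
})

test_that("stratified_kfold partitions with balanced classes", {
  lab <- data.frame(molecule_id = sprintf("m%02d", rep(1:20, each = 5)),
                    chain_id = "HC", position = rep(1:5, 20),
                    label = rep(c("active", "inactive"),
                                times = c(12, 88)))
  folds <- stratified_kfold(lab, 5, seed = 3)
  # partition: disjoint cover
  expect_equal(sort(unlist(folds)), 1:100)
  expect_equal(max(table(unlist(folds))), 1)
  for (f in folds) {
    expect_equal(length(f), 20)
    expect_true(sum(lab$label[f] == "active") %in% 2:3)
  }
  # seeded determinism and invariance to row order
  perm <- sample(100)
  folds_perm <- stratified_kfold(lab[perm, ], 5, seed = 3)
  sites_of <- function(d, ix) sort(paste(d$molecule_id[ix], d$position[ix]))
  for (j in 1:5) {
    expect_equal(sites_of(lab, folds[[j]]),
                 sites_of(lab[perm, ], folds_perm[[j]]))
  }
  # exact stratification of a balanced 4-site set
  lab4 <- data.frame(molecule_id = "m", chain_id = "c", position = 1:4,
                     label = c("active", "active", "inactive", "inactive"))
  f2 <- stratified_kfold(lab4, 2, seed = 1)
  for (f in f2) expect_equal(sort(lab4$label[f]), c("active", "inactive"))
  expect_error(stratified_kfold(lab4, 3, seed = 1),
               class = "deamid_validation_error")
})

test_that("cross_validate aggregates per-fold metrics", {
  sim <- small_world(5)
  lab <- label_sites(sim$timecourse)
  cfg <- fast_config(max_epochs = 8L)
  cv <- cross_validate(sim$chains, lab, "global_only", cfg, k = 3)
  expect_equal(nrow(cv$per_fold), 3)
  expect_equal(cv$mean[["accuracy"]], mean(cv$per_fold$accuracy))
  expect_equal(cv$sd[["mcc"]], sd(cv$per_fold$mcc))
  # deterministic rerun
  cv2 <- cross_validate(sim$chains, lab, "global_only", cfg, k = 3)
  expect_identical(cv$per_fold, cv2$per_fold)
})

test_that("window_sweep returns one row per size and tracks the argmax", {
  sim <- small_world(5)
  lab <- label_sites(sim$timecourse)
  cfg <- fast_config(max_epochs = 8L)
  sw <- window_sweep(sim$chains, lab, c(3, 5), cfg, k = 3)
  expect_equal(sw$window_size, c(3, 5))
  expect_equal(attr(sw, "best"), sw$window_size[which.max(sw$mcc)])
  sw1 <- window_sweep(sim$chains, lab, 3, cfg, k = 3)
  expect_equal(nrow(sw1), 1)
  expect_error(window_sweep(sim$chains, lab, c(4, 6), cfg),
               class = "deamid_validation_error")
})
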