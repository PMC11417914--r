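test_that("build_model wires the configured widths", {
  cfg <- run_config(token_dim = 8, lstm_hidden = 16, hidden1 = 64,
                    hidden2 = 32)
  m <- build_model("chimeric", "classification", cfg, d = 1280)
  # head input = global d + 2 x recurrent hidden
  expect_equal(nrow(m$weights$W1), 1280 + 2 * 16)
  expect_equal(dim(m$weights$Emb), c(22, 8))
  expect_equal(ncol(m$weights$W3), 1)
  r <- build_model("chimeric", "regression", cfg, d = 32)
  expect_equal(ncol(r$weights$W3), 3)
  g <- build_model("global_only", "classification", cfg, d = 32)
  expect_null(g$weights$Emb)
  expect_error(build_model("chimeric", "classification", cfg, d = 0),
               class = "deamid_config_error")
})

test_that("training is seeded and deterministic end to end", {
  sim <- small_world(4)
  lab <- label_sites(sim$timecourse)
  cfg <- fast_config(max_epochs = 10L)
  m1 <- fit_deamid(sim$chains, lab, "chimeric", "classification", cfg)
  m2 <- fit_deamid(sim$chains, lab, "chimeric", "classification", cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$weights$W1, m2$weights$W1)
  # a different seed moves the trajectory
  m3 <- fit_deamid(sim$chains, lab, "chimeric", "classification",
                   fast_config(seed = 2L, max_epochs = 10L))
  expect_false(identical(m1$history$train_loss, m3$history$train_loss))
})

test_that("early stopping keeps the best epoch and honours patience", {
  sim <- small_world(4)
  lab <- label_sites(sim$timecourse)
  cfg <- fast_config(max_epochs = 50L)
  cfg$patience <- 0L
  m <- fit_deamid(sim$chains, lab, "global_only", "classification", cfg)
  # patience 0: stops exactly one epoch after the last improvement
  expect_true(m$epochs_run == m$best_epoch + 1 ||
                m$epochs_run == cfg$max_epochs)
  expect_equal(m$history$val_loss[m$best_epoch], min(m$history$val_loss))
})

test_that("single-class training splits are rejected", {
  sim <- small_world(3)
  lab <- label_sites(sim$timecourse)
  lab$label <- "inactive"
  expect_error(fit_deamid(sim$chains, lab, "global_only", "classification",
                          fast_config()),
               "single class", class = "deamid_training_error")
})

test_that("training fits a linearly separable problem", {
  # constructed oracle: a global feature that encodes the label directly
  set.seed(3)
  n <- 300
  y <- rep(c("active", "inactive"), length.out = n)
  G <- matrix(rnorm(n * 8, sd = 0.1), n, 8)
  G[, 1] <- ifelse(y == "active", 1, -1)
  labeled <- data.frame(molecule_id = "m", chain_id = "c",
                        position = seq_len(n), residue = "N", label = y)
  feats <- structure(list(global = G, tokens = NULL, sites = labeled),
                     class = "deamid_features")
  cfg <- fast_config(max_epochs = 60L, patience = 60L)
  model <- build_model("global_only", "classification", cfg, d = 8)
  idx <- deamidr:::val_split(labeled, 0.1, cfg$seed)
  fit <- train_model(model,
                     deamidr:::subset_features(feats, idx$train),
                     labeled[idx$train, ],
                     deamidr:::subset_features(feats, idx$val),
                     labeled[idx$val, ])
  pred <- predict(fit, feats)
  expect_equal(mean(pred$predicted_label == y), 1.0)
})

test_that("predictions honour bounds, thresholds and clamping", {
  sim <- small_world(4)
  lab <- label_sites(sim$timecourse)
  cfg <- fast_config(max_epochs = 10L)
  emb <- make_mock_embedder(32, cfg$seed)
  feats <- featurize_sites(sim$chains, lab, emb, cfg$window_size)
  m <- fit_deamid(sim$chains, lab, "chimeric", "classification", cfg)
  p <- predict(m, feats)
  expect_true(all(p$probability >= 0 & p$probability <= 1))
  expect_equal(p$predicted_label,
               ifelse(p$probability > cfg$decision_threshold,
                      "active", "inactive"))
  r <- fit_deamid(sim$chains, lab, "chimeric", "regression", cfg)
  pr <- predict(r, feats)
  for (col in c("pred_extent_2wk", "pred_extent_4wk", "pred_extent_8wk")) {
    expect_true(all(pr[[col]] >= 0 & pr[[col]] <= 100))
  }
})

test_that("global_only predictions ignore window content", {
  sim <- small_world(3)
  lab <- label_sites(sim$timecourse)
  cfg <- fast_config(max_epochs = 5L)
  emb <- make_mock_embedder(32, cfg$seed)
  m <- fit_deamid(sim$chains, lab, "global_only", "classification", cfg)
  f1 <- featurize_sites(sim$chains, lab, emb, NULL)
  p1 <- predict(m, f1)
  f2 <- f1; f2$tokens <- matrix(1L, nrow(lab), 31)  # irrelevant windows
  expect_identical(predict(m, f2)$probability, p1$probability)
})

test_that("feature dimension mismatches raise shape errors", {
  sim <- small_world(3)
  lab <- label_sites(sim$timecourse)
  cfg <- fast_config(max_epochs = 3L)
  m <- fit_deamid(sim$chains, lab, "chimeric", "classification", cfg)
  bad <- featurize_sites(sim$chains, lab, make_mock_embedder(16, 1),
                         cfg$window_size)
  expect_error(predict(m, bad), "expected 32, got 16",
               class = "deamid_shape_error")
})

test_that("checkpoints round trip through save_model/load_model", {
  sim <- small_world(3)
  lab <- label_sites(sim$timecourse)
  cfg <- fast_config(max_epochs = 5L)
  m <- fit_deamid(sim$chains, lab, "chimeric", "classification", cfg)
  dir <- withr::local_tempdir()
  save_model(m, dir)
  m2 <- load_model(dir)
  feats <- featurize_sites(sim$chains, lab, make_mock_embedder(32, cfg$seed),
                           cfg$window_size)
  expect_equal(predict(m2, feats), predict(m, feats), tolerance = 1e-12)
  expect_equal(m2$variant, m$variant)
  expect_error(load_model(withr::local_tempdir()), class = "deamid_io_error")
})
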