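# The three model variants -- global-only DNN, local-only window encoder,
# and the chimeric meta-classifier -- plus the 3-timepoint extent-regression
# head. The numerical core (BiLSTM + fully connected head, Adam, dropout,
# early stopping) lives in src/nn.cpp; this file owns initialisation,
# featurisation, the training protocol and checkpoints.

MODEL_VARIANTS <- c("global_only", "local_only", "chimeric")
MODEL_TASKS <- c("classification", "regression")

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

#' Build an untrained model
#'
#' * `global_only`: frozen pLM site vector -> two hidden layers with
#'   dropout -> head.
#' * `local_only`: token window -> learned embedding -> BiLSTM -> head.
#' * `chimeric`: concatenation of the global site vector and the BiLSTM
#'   window summary -> fully connected head.
#'
#' The classification head outputs one probability; the regression head
#' outputs three extents (t = 2, 4, 8 weeks). Weights are initialised with
#' the seed in `config`.
#'
#' @param variant one of `"global_only"`, `"local_only"`, `"chimeric"`.
#' @param task `"classification"` or `"regression"`.
#' @param config a [run_config()].
#' @param d global embedding dimension (ignored by `local_only`).
#' @return An untrained object of class `deamid_model`.
#' @export
build_model <- function(variant = MODEL_VARIANTS, task = MODEL_TASKS,
                        config = run_config(), d = NULL) {
  variant <- match.arg(variant)
  task <- match.arg(task)
  use_global <- variant %in% c("global_only", "chimeric")
  use_local <- variant %in% c("local_only", "chimeric")
  if (use_global) {
    assert_that(!is.null(d) && d >= 1, "embedding dimension d must be >= 1",
                class = "deamid_config_error")
    d <- as.integer(d)
  } else {
    d <- 0L
  }
  vocab_n <- length(AA_ALPHABET) + 1L  # + PAD
  e <- config$token_dim
  h <- config$lstm_hidden
  zdim <- d + if (use_local) 2L * h else 0L
  out <- if (task == "classification") 1L else 3L
  weights <- with_seed(config$seed, {
    w <- list(use_global = use_global, use_local = use_local,
              task = task, d = d)
    if (use_local) {
      w$Emb <- matrix(runif(vocab_n * e, -0.05, 0.05), vocab_n, e)
      for (dir in c("f", "b")) {
        w[[paste0("Wx", dir)]] <- glorot(e, 4L * h)
        w[[paste0("Wh", dir)]] <- glorot(h, 4L * h)
        b <- numeric(4L * h)
        b[(h + 1L):(2L * h)] <- 1  # forget-gate bias
        w[[paste0("b", dir)]] <- b
      }
    }
    w$W1 <- glorot(zdim, config$hidden1); w$b1 <- numeric(config$hidden1)
    w$W2 <- glorot(config$hidden1, config$hidden2); w$b2 <- numeric(config$hidden2)
    w$W3 <- glorot(config$hidden2, out); w$b3 <- numeric(out)
    w
  })
  structure(list(variant = variant, task = task, config = config,
                 d = d, w = if (use_local) config$window_size else NA_integer_,
                 embedder_name = config$embedder_name,
                 weights = weights, trained = FALSE,
                 epochs_run = NA_integer_, best_epoch = NA_integer_,
                 history = NULL),
            class = "deamid_model")
}

#' Featurize candidate sites for a model variant
#'
#' @param chains chain data frame.
#' @param sites data frame with `molecule_id`, `chain_id`, `position`.
#' @param embedder a `deamid_embedder` (required for global features),
#'   or `NULL`.
#' @param window_size odd window width (required for local features),
#'   or `NULL`.
#' @return A list of class `deamid_features` with `global` (n x d matrix or
#'   `NULL`), `tokens` (n x w integer matrix or `NULL`) and `sites`.
#' @export
featurize_sites <- function(chains, sites, embedder = NULL, window_size = NULL) {
  global <- NULL
  if (!is.null(embedder)) {
    key <- paste(chains$molecule_id, chains$chain_id, sep = "|")
    hit <- match(paste(sites$molecule_id, sites$chain_id, sep = "|"), key)
    assert_that(!anyNA(hit), "sites reference unknown chains",
                class = "deamid_validation_error")
    global <- matrix(0, nrow(sites), embedder$d)
    for (ci in unique(hit)) {
      emb <- embed_chain(embedder, chains[ci, ])
      rows <- which(hit == ci)
      global[rows, ] <- emb$vectors[sites$position[rows], , drop = FALSE]
    }
  }
  tokens <- if (!is.null(window_size)) window_matrix(chains, sites, window_size)
  structure(list(global = global, tokens = tokens, sites = sites),
            class = "deamid_features")
}

subset_features <- function(features, idx) {
  structure(list(global = if (!is.null(features$global)) features$global[idx, , drop = FALSE],
                 tokens = if (!is.null(features$tokens)) features$tokens[idx, , drop = FALSE],
                 sites = features$sites[idx, , drop = FALSE]),
            class = "deamid_features")
}

model_inputs <- function(model, features) {
  G <- NULL; tok <- NULL
  if (model$variant %in% c("global_only", "chimeric")) {
    assert_that(!is.null(features$global), "model needs global features",
                class = "deamid_shape_error")
    assert_that(ncol(features$global) == model$d,
                "global dimension mismatch: expected ", model$d, ", got ",
                ncol(features$global), class = "deamid_shape_error")
    G <- features$global
  }
  if (model$variant %in% c("local_only", "chimeric")) {
    assert_that(!is.null(features$tokens), "model needs local windows",
                class = "deamid_shape_error")
    assert_that(ncol(features$tokens) == model$w,
                "window size mismatch: expected ", model$w, ", got ",
                ncol(features$tokens), class = "deamid_shape_error")
    tok <- features$tokens
    storage.mode(tok) <- "integer"
  }
  list(G = G, tok = tok)
}

response_matrix <- function(model, labeled) {
  if (model$task == "classification") {
    assert_that(all(labeled$label %in% c("active", "inactive")),
                "labels must be active/inactive",
                class = "deamid_validation_error")
    matrix(as.numeric(labeled$label == "active"), ncol = 1)
  } else {
    # extents scaled to [0, 1]; NA targets are masked out of the loss
    as.matrix(labeled[, c("pct_2wk", "pct_4wk", "pct_8wk")]) / 100
  }
}

#' Train a model
#'
#' Minimises binary cross-entropy (classification) or mean squared error on
#' the measured extents (regression) with Adam, dropout, and early stopping
#' on the validation loss: training stops once the validation objective has
#' failed to improve for more than `patience` consecutive epochs, and the
#' weights of the best validation epoch are kept. Fully reproducible for a
#' fixed seed.
#'
#' @param model an untrained model from [build_model()].
#' @param features training features from [featurize_sites()].
#' @param labeled training labels (data frame with `label` and, for
#'   regression, `pct_2wk`, `pct_4wk`, `pct_8wk`).
#' @param val_features,val_labeled validation split used for early stopping
#'   (must be disjoint from training by site).
#' @return The trained `deamid_model`, with `history`, `best_epoch` and
#'   `epochs_run` populated.
#' @export
train_model <- function(model, features, labeled, val_features, val_labeled) {
  stopifnot(inherits(model, "deamid_model"))
  cfg <- model$config
  Y <- response_matrix(model, labeled)
  Yv <- response_matrix(model, val_labeled)
  if (model$task == "classification") {
    assert_that(length(unique(Y[, 1])) == 2,
                "training split contains a single class; ",
                "use a stratified split", class = "deamid_training_error")
  }
  tr <- model_inputs(model, features)
  va <- model_inputs(model, val_features)
  fit <- with_seed(cfg$seed, {
    nn_train_cpp(model$weights, tr$G, tr$tok, Y, va$G, va$tok, Yv,
                 cfg$learning_rate, cfg$batch_size, cfg$max_epochs,
                 cfg$patience, cfg$dropout, cfg$pos_weight %||% 1)
  })
  model$weights <- fit$weights
  model$trained <- TRUE
  model$epochs_run <- fit$epochs_run
  model$best_epoch <- fit$best_epoch
  model$history <- data.frame(epoch = seq_along(fit$train_loss),
                              train_loss = fit$train_loss,
                              val_loss = fit$val_loss)
  model
}

#' Predict deamidation outcomes for featurized sites
#'
#' @param object a trained `deamid_model`.
#' @param features a `deamid_features` object for the same variant.
#' @param ... unused.
#' @return A data frame of site predictions. Classification models report
#'   `probability` and `predicted_label` (active iff probability strictly
#'   exceeds the configured decision threshold); regression models report
#'   `pred_extent_2wk`, `pred_extent_4wk`, `pred_extent_8wk`, clamped to
#'   [0, 100].
#' @export
predict.deamid_model <- function(object, features, ...) {
  assert_that(isTRUE(object$trained), "model is not trained",
              class = "deamid_validation_error")
  inp <- model_inputs(object, features)
  O <- nn_forward_cpp(object$weights, inp$G, inp$tok)
  s <- features$sites
  out <- data.frame(molecule = s$molecule_id, chain = s$chain_id,
                    position = s$position,
                    residue = s$residue %||% NA_character_,
                    stringsAsFactors = FALSE)
  if (object$task == "classification") {
    out$probability <- O[, 1]
    out$predicted_label <- ifelse(O[, 1] > object$config$decision_threshold,
                                  "active", "inactive")
  } else {
    ext <- pmin(pmax(O * 100, 0), 100)
    out$pred_extent_2wk <- ext[, 1]
    out$pred_extent_4wk <- ext[, 2]
    out$pred_extent_8wk <- ext[, 3]
  }
  out
}

#' @export
print.deamid_model <- function(x, ...) {
  cat(sprintf("deamid_model: %s / %s (%s)\n", x$variant, x$task,
              if (x$trained) sprintf("trained, best epoch %d of %d run",
                                     x$best_epoch, x$epochs_run)
              else "untrained"))
  if (x$variant != "local_only") cat("  global dim:", x$d, "\n")
  if (x$variant != "global_only") cat("  window size:", x$w, "\n")
  invisible(x)
}

#' Save a trained model checkpoint
#'
#' Writes a directory with `weights.json` (full-precision parameters) and
#' `meta.json` (variant, task, configuration, embedder name, seed, epochs).
#'
#' @param model a `deamid_model`.
#' @param dir checkpoint directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(model$weights, file.path(dir, "weights.json"),
                       digits = NA, auto_unbox = TRUE)
  meta <- model[c("variant", "task", "d", "w", "embedder_name",
                  "trained", "epochs_run", "best_epoch")]
  meta$config <- unclass(model$config)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Load a model checkpoint written by [save_model()]
#' @param dir checkpoint directory.
#' @return A `deamid_model`.
#' @export
load_model <- function(dir) {
  wpath <- file.path(dir, "weights.json")
  mpath <- file.path(dir, "meta.json")
  assert_that(file.exists(wpath) && file.exists(mpath),
              "not a model checkpoint: ", dir, class = "deamid_io_error")
  w <- jsonlite::read_json(wpath, simplifyVector = TRUE)
  for (nm in names(w)) if (is.numeric(w[[nm]]) && !is.matrix(w[[nm]]) &&
                           nm %in% c("Emb", "Wxf", "Whf", "Wxb", "Whb",
                                     "W1", "W2", "W3")) {
    w[[nm]] <- as.matrix(w[[nm]])
  }
  meta <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  cfg <- do.call(run_config,
                 meta$config[intersect(names(meta$config),
                                       names(formals(run_config)))])
  structure(list(variant = meta$variant, task = meta$task, config = cfg,
                 d = as.integer(meta$d), w = as.integer(meta$w),
                 embedder_name = meta$embedder_name, weights = w,
                 trained = isTRUE(meta$trained),
                 epochs_run = meta$epochs_run, best_epoch = meta$best_epoch,
                 history = NULL),
            class = "deamid_model")
}

#' Train a model from a labeled dataset in one call
#'
#' Convenience wrapper: featurizes all sites, carves out a stratified
#' validation split for early stopping, and trains.
#'
#' @param chains chain data frame.
#' @param labeled labeled dataset from [build_dataset()] or [label_sites()].
#' @param variant,task see [build_model()].
#' @param config a [run_config()].
#' @param embedder backend for global features; defaults to the backend
#'   named in `config` (must be a mock identifier).
#' @return A trained `deamid_model`.
#' @export
fit_deamid <- function(chains, labeled, variant = "chimeric",
                       task = "classification", config = run_config(),
                       embedder = NULL) {
  if (is.null(embedder) && variant != "local_only") {
    embedder <- embedder_from_name(config$embedder_name)
  }
  features <- featurize_sites(
    chains, labeled,
    embedder = if (variant != "local_only") embedder,
    window_size = if (variant != "global_only") config$window_size)
  d <- if (variant == "local_only") NULL else embedder$d
  model <- build_model(variant, task, config, d = d)
  idx <- val_split(labeled, config$val_fraction, config$seed,
                   stratify = task == "classification")
  train_model(model,
              subset_features(features, idx$train), labeled[idx$train, ],
              subset_features(features, idx$val), labeled[idx$val, ])
}

# Stratified validation split; returns list(train=, val=) of row indices.
val_split <- function(labeled, fraction, seed, stratify = TRUE) {
  n <- nrow(labeled)
  with_seed(seed + 10007L, {
    if (stratify && "label" %in% names(labeled)) {
      val <- unlist(lapply(split(seq_len(n), labeled$label), function(ix) {
        k <- max(1L, round(length(ix) * fraction))
        sample(ix, k)
      }), use.names = FALSE)
    } else {
      val <- sample(n, max(1L, round(n * fraction)))
    }
    list(train = setdiff(seq_len(n), val), val = sort(val))
  })
}
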