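#' Run configuration
#'
#' Collects every tunable of the workflow: windowing, labeling and decision
#' thresholds, the embedder backend, and the training hyperparameters of
#' the neural models. All values have working defaults; the local-window
#' size defaults to 31 residues, the plateau of the window-size sweep.
#'
#' @param window_size odd integer >= 3; width of the local sequence window.
#' @param embedder_name backend identifier, e.g. `"mock_d32_s1"`.
#' @param label_threshold percent increment above which an early time-course
#'   step marks a site as a hot spot (default 1.0).
#' @param decision_threshold probability cut-off for calling a site active
#'   (strictly greater than; default 0.5).
#' @param seed integer seed controlling folds, initialisation, shuffling
#'   and dropout.
#' @param token_dim dimension of the learned window token embedding.
#' @param lstm_hidden hidden width per direction of the window encoder.
#' @param hidden1,hidden2 widths of the two fully connected head layers.
#' @param dropout dropout rate applied after each head layer.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement tolerated before stopping).
#' @param val_fraction fraction of each training split held out for early
#'   stopping.
#' @param pos_weight weight of the active class in the cross-entropy loss
#'   (1 = no re-weighting, the default; the switch exists for synthetic
#'   experiments on heavily imbalanced worlds).
#' @return An object of class `deamid_config` (a validated list).
#' @examples
#' cfg <- run_config(window_size = 11, seed = 42)
#' cfg$window_size
#' @export
run_config <- function(window_size = 31L,
                       embedder_name = "mock_d32_s1",
                       label_threshold = 1.0,
                       decision_threshold = 0.5,
                       seed = 1L,
                       token_dim = 16L,
                       lstm_hidden = 64L,
                       hidden1 = 256L,
                       hidden2 = 64L,
                       dropout = 0.3,
                       learning_rate = 1e-3,
                       batch_size = 64L,
                       max_epochs = 200L,
                       patience = 10L,
                       val_fraction = 0.1,
                       pos_weight = 1) {
  cfg <- list(window_size = as.integer(window_size),
              embedder_name = embedder_name,
              label_threshold = label_threshold,
              decision_threshold = decision_threshold,
              seed = as.integer(seed),
              token_dim = as.integer(token_dim),
              lstm_hidden = as.integer(lstm_hidden),
              hidden1 = as.integer(hidden1),
              hidden2 = as.integer(hidden2),
              dropout = dropout,
              learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience),
              val_fraction = val_fraction,
              pos_weight = pos_weight)
  validate_config(cfg)
  structure(cfg, class = "deamid_config")
}

validate_config <- function(cfg) {
  assert_that(cfg$window_size >= 3 && cfg$window_size %% 2 == 1,
              "window_size must be an odd integer >= 3",
              class = "deamid_validation_error")
  assert_that(cfg$label_threshold >= 0, "label_threshold must be >= 0",
              class = "deamid_validation_error")
  assert_that(cfg$decision_threshold >= 0 && cfg$decision_threshold <= 1,
              "decision_threshold must be in [0, 1]",
              class = "deamid_validation_error")
  assert_that(cfg$dropout >= 0 && cfg$dropout < 1,
              "dropout must be in [0, 1)", class = "deamid_validation_error")
  assert_that(cfg$patience >= 0, "patience must be >= 0",
              class = "deamid_validation_error")
  assert_that(cfg$val_fraction > 0 && cfg$val_fraction < 1,
              "val_fraction must be in (0, 1)",
              class = "deamid_validation_error")
  assert_that(cfg$pos_weight > 0, "pos_weight must be > 0",
              class = "deamid_validation_error")
  invisible(cfg)
}

#' Desk-scale benchmark configuration
#'
#' The configuration used by this package's own synthetic benchmarks and
#' acceptance checks: the same architecture as [run_config()] but with
#' smaller widths (token dim 8, LSTM hidden 16, head 64 -> 32, mock
#' embedder d = 32), a faster learning rate (5e-3) and a longer early
#' stopping patience (20), so a full cross-validation of all three model
#' variants runs in minutes on one CPU. See the methods vignette for the
#' rationale.
#'
#' @param seed integer seed; also selects the mock embedder basis.
#' @param window_size odd local window size (default 31).
#' @param ... further overrides passed to [run_config()].
#' @return A `deamid_config`.
#' @export
benchmark_config <- function(seed = 7L, window_size = 31L, ...) {
  args <- modifyList(
    list(window_size = window_size, token_dim = 8L, lstm_hidden = 16L,
         hidden1 = 64L, hidden2 = 32L, max_epochs = 200L, patience = 20L,
         learning_rate = 5e-3, seed = seed,
         embedder_name = sprintf("mock_d32_s%d", as.integer(seed))),
    list(...))
  do.call(run_config, args)
}

#' Write a run configuration to YAML or JSON
#'
#' The format is chosen from the file extension (`.yml`/`.yaml` or `.json`).
#'
#' @param config a [run_config()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  x <- unclass(config)
  if (ext %in% c("yml", "yaml")) {
    yaml::write_yaml(x, path)
  } else if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop_deamid("unsupported config extension: .", ext,
                class = "deamid_io_error")
  }
  invisible(path)
}

#' Read a run configuration from YAML or JSON
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A `deamid_config` object; unknown keys are ignored, missing keys
#'   take their defaults.
#' @export
read_run_config <- function(path) {
  assert_that(file.exists(path), "no such file: ", path,
              class = "deamid_io_error")
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop_deamid("unsupported config extension: .", ext,
                class = "deamid_io_error")
  }
  do.call(run_config, x[intersect(names(x), names(formals(run_config)))])
}
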