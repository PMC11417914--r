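# FASTA-only screening: enumerate every N/Q site of a clone panel, predict
# hot-spot probabilities and projected extents, and aggregate per chain.

#' Screen a clone panel from sequences alone
#'
#' Enumerates all N/Q sites of every input chain, predicts the hot-spot
#' probability with the classifier and (optionally) the deamidation extents
#' at 2/4/8 weeks with the regressor, and aggregates per chain the summed
#' predicted extents over predicted hot spots. Chains whose 8-week
#' aggregate is below `low_threshold` are flagged as low-liability.
#'
#' @param chains chain data frame (e.g. from [read_fasta()]).
#' @param classifier trained classification `deamid_model`.
#' @param regressor optional trained regression `deamid_model`.
#' @param embedder backend; defaults to the one recorded in the classifier
#'   metadata (works for mock identifiers).
#' @param low_threshold percent; 8-week aggregate below this flags a chain
#'   as low deamidation liability (default 5).
#' @return A list of class `deamid_screen`: `sites` (long-format
#'   per-site predictions) and `aggregate` (per-chain totals with a
#'   `low_liability` flag).
#' @export
screen_sequences <- function(chains, classifier, regressor = NULL,
                             embedder = NULL, low_threshold = 5) {
  stopifnot(inherits(classifier, "deamid_model"))
  assert_that(classifier$task == "classification",
              "classifier must be a classification model",
              class = "deamid_validation_error")
  if (is.null(embedder) && classifier$variant != "local_only") {
    embedder <- embedder_from_name(classifier$embedder_name)
  }
  sites <- do.call(rbind, lapply(seq_len(nrow(chains)), function(i) {
    s <- enumerate_candidate_sites(chains$sequence[i])
    if (nrow(s) == 0) return(NULL)
    cbind(data.frame(molecule_id = chains$molecule_id[i],
                     chain_id = chains$chain_id[i],
                     stringsAsFactors = FALSE), s)
  }))
  if (is.null(sites)) {
    sites <- data.frame(molecule_id = character(), chain_id = character(),
                        position = integer(), residue = character())
  }
  fz <- function(model) featurize_sites(
    chains, sites,
    embedder = if (model$variant != "local_only") embedder,
    window_size = if (model$variant != "global_only") model$w)
  pred <- predict(classifier, fz(classifier))
  if (!is.null(regressor)) {
    assert_that(regressor$task == "regression",
                "regressor must be a regression model",
                class = "deamid_validation_error")
    reg <- predict(regressor, fz(regressor))
    pred$pred_extent_2wk <- reg$pred_extent_2wk
    pred$pred_extent_4wk <- reg$pred_extent_4wk
    pred$pred_extent_8wk <- reg$pred_extent_8wk
  } else {
    pred$pred_extent_2wk <- NA_real_
    pred$pred_extent_4wk <- NA_real_
    pred$pred_extent_8wk <- NA_real_
  }
  agg <- do.call(rbind, lapply(split(pred, paste(pred$molecule, pred$chain,
                                                 sep = "|")), function(g) {
    hot <- g[g$predicted_label == "active", , drop = FALSE]
    sum0 <- function(v) if (nrow(hot) == 0 || all(is.na(v))) 0 else sum(v, na.rm = TRUE)
    data.frame(molecule = g$molecule[1], chain = g$chain[1],
               n_sites = nrow(g), n_hotspots = nrow(hot),
               agg_extent_2wk = sum0(hot$pred_extent_2wk),
               agg_extent_4wk = sum0(hot$pred_extent_4wk),
               agg_extent_8wk = sum0(hot$pred_extent_8wk),
               stringsAsFactors = FALSE)
  }))
  # keep chain input order
  ord <- match(paste(chains$molecule_id, chains$chain_id, sep = "|"),
               paste(agg$molecule, agg$chain, sep = "|"))
  agg <- agg[ord[!is.na(ord)], , drop = FALSE]
  rownames(agg) <- NULL
  agg$low_liability <- agg$agg_extent_8wk < low_threshold
  structure(list(sites = pred, aggregate = agg), class = "deamid_screen")
}
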