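# The canonical NG/NS/NN motif baseline and the motif-probing
# interpretability routine for the local sequence model.

#' Canonical deamidation motif rule
#'
#' @param motifs dipeptides flagged as deamidation-prone; each must start
#'   with N. Default: the canonical NG, NS, NN.
#' @return An object of class `deamid_motif_rule`.
#' @export
motif_rule <- function(motifs = c("NG", "NS", "NN")) {
  assert_that(all(nchar(motifs) == 2 & startsWith(motifs, "N")),
              "motifs must be dipeptides starting with N",
              class = "deamid_validation_error")
  structure(list(motifs = unique(motifs)), class = "deamid_motif_rule")
}

#' Classify one site with the motif rule
#'
#' A site is called active iff it is an asparagine whose (N, successor)
#' dipeptide is in the rule set. Glutamine sites and chain-terminal N (no
#' successor) are always inactive.
#'
#' @param chain amino-acid string or one-row chain data frame.
#' @param position 1-based site index (residue must be N or Q).
#' @param rule a [motif_rule()].
#' @return `"active"` or `"inactive"`.
#' @examples
#' motif_classify("ANGS", 2)
#' @export
motif_classify <- function(chain, position, rule = motif_rule()) {
  seq <- if (is.character(chain) && length(chain) == 1) chain else chain$sequence
  res <- substring(seq, position, position)
  assert_that(res %in% c("N", "Q"), "site must be N or Q, found '", res, "'",
              class = "deamid_validation_error")
  if (res != "N" || position >= nchar(seq)) return("inactive")
  dipep <- substring(seq, position, position + 1)
  if (dipep %in% rule$motifs) "active" else "inactive"
}

#' Classify every site of a dataset with the motif rule
#'
#' @param chains chain data frame.
#' @param sites data frame with `molecule_id`, `chain_id`, `position`.
#' @param rule a [motif_rule()].
#' @return `sites` with an added `predicted_label` column.
#' @export
motif_classify_sites <- function(chains, sites, rule = motif_rule()) {
  key <- paste(chains$molecule_id, chains$chain_id, sep = "|")
  hit <- match(paste(sites$molecule_id, sites$chain_id, sep = "|"), key)
  assert_that(!anyNA(hit), "sites reference unknown chains",
              class = "deamid_validation_error")
  sites$predicted_label <- vapply(seq_len(nrow(sites)), function(i) {
    motif_classify(chains$sequence[hit[i]], sites$position[i], rule)
  }, "")
  sites
}

#' Probe a trained local model for its learned motif preferences
#'
#' For each of the 20 amino acids, builds a probe window whose context is
#' entirely PAD except for an N at the center and the probed residue at the
#' X+1 (successor) or X-1 (predecessor) slot, and scores it with the model.
#' The neutral PAD context isolates the marginal effect of the probed slot.
#'
#' @param model a trained `local_only` classification model with window
#'   size >= 3.
#' @param direction `"x_plus_1"` or `"x_minus_1"`.
#' @return A data frame `(motif, direction, score)` with exactly 20 rows,
#'   sorted by descending score.
#' @export
probe_motifs <- function(model, direction = c("x_plus_1", "x_minus_1")) {
  direction <- match.arg(direction)
  stopifnot(inherits(model, "deamid_model"))
  assert_that(isTRUE(model$trained), "model is not trained",
              class = "deamid_validation_error")
  assert_that(model$variant == "local_only" &&
                model$task == "classification",
              "probe requires a trained local_only classifier",
              class = "deamid_validation_error")
  w <- model$w
  center <- (w + 1L) %/% 2L
  slot <- if (direction == "x_plus_1") center + 1L else center - 1L
  tok <- matrix(0L, 20L, w)
  tok[, center] <- tokenize_residues("N")
  tok[, slot] <- tokenize_residues(AA20)
  probs <- nn_forward_cpp(model$weights, NULL, tok)[, 1]
  motif <- if (direction == "x_plus_1") paste0("N", AA20) else paste0(AA20, "N")
  out <- data.frame(motif = motif, direction = direction, score = probs,
                    stringsAsFactors = FALSE)
  out[order(-out$score), , drop = FALSE]
}
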