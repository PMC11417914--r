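# Local sequence windows: fixed-width token windows centered on candidate
# sites, fed to the learned token-embedding + BiLSTM encoder.

#' Extract the local sequence window around a site
#'
#' The window covers (w-1)/2 residues on each side of the site; positions
#' beyond the chain termini are filled with PAD tokens (id 0), so windows
#' never cross chain boundaries and all windows have identical length.
#'
#' @param chain an amino-acid string or one-row chain data frame.
#' @param position 1-based index of the site (must be N or Q).
#' @param w odd window size, 3 to 61.
#' @return A list of class `deamid_window` with `tokens` (integer vector of
#'   length `w`), `center_index` ((w-1)/2, 0-based), and provenance.
#' @examples
#' extract_window("ADNGS", 3, 3)$tokens
#' @export
extract_window <- function(chain, position, w) {
  seq <- if (is.character(chain) && length(chain) == 1) chain else chain$sequence
  n <- nchar(seq)
  assert_that(w %% 2 == 1 && w >= 3 && w <= 61,
              "window size must be odd and in [3, 61], got ", w,
              class = "deamid_validation_error")
  assert_that(position >= 1 && position <= n,
              "position ", position, " out of range",
              class = "deamid_index_error")
  center <- substring(seq, position, position)
  assert_that(center %in% c("N", "Q"),
              "window center must be N or Q, found '", center,
              "' at position ", position, class = "deamid_validation_error")
  half <- (w - 1L) %/% 2L
  idx <- (position - half):(position + half)
  tokens <- integer(w)
  in_range <- idx >= 1 & idx <= n
  tokens[in_range] <- tokenize_residues(
    strsplit(substring(seq, max(1, position - half),
                       min(n, position + half)), "")[[1]])
  structure(list(tokens = as.integer(tokens), center_index = half,
                 molecule_id = if (is.list(chain)) chain$molecule_id else NA_character_,
                 chain_id = if (is.list(chain)) chain$chain_id else NA_character_,
                 position = as.integer(position)),
            class = "deamid_window")
}

# All windows for a site table, as an n x w integer token matrix.
window_matrix <- function(chains, sites, w) {
  key <- paste(chains$molecule_id, chains$chain_id, sep = "|")
  hit <- match(paste(sites$molecule_id, sites$chain_id, sep = "|"), key)
  assert_that(!anyNA(hit), "sites reference unknown chains",
              class = "deamid_validation_error")
  out <- matrix(0L, nrow(sites), w)
  for (i in seq_len(nrow(sites))) {
    out[i, ] <- extract_window(chains$sequence[hit[i]], sites$position[i], w)$tokens
  }
  out
}

#' Encode local windows with a trained model's local branch
#'
#' Runs the token embedding and bidirectional LSTM of a trained model and
#' returns the window summary vectors (final forward and backward hidden
#' states, concatenated).
#'
#' @param windows an n x w integer token matrix, a single `deamid_window`,
#'   or a list of them.
#' @param model a trained model containing a local branch
#'   (`local_only` or `chimeric` variant).
#' @return An n x (2 * hidden width) numeric matrix, one row per window.
#' @export
encode_local <- function(windows, model) {
  stopifnot(inherits(model, "deamid_model"))
  assert_that(model$variant %in% c("local_only", "chimeric"),
              "model has no local branch", class = "deamid_validation_error")
  tok <- windows
  if (inherits(windows, "deamid_window")) tok <- matrix(windows$tokens, 1)
  if (is.list(tok) && !is.matrix(tok)) {
    tok <- do.call(rbind, lapply(tok, function(x) x$tokens))
  }
  assert_that(ncol(tok) == model$w,
              "window length ", ncol(tok), " does not match encoder width ",
              model$w, class = "deamid_shape_error")
  storage.mode(tok) <- "integer"
  nn_local_cpp(model$weights, tok)
}
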