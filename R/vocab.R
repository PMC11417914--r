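# Token vocabulary shared by the local-window encoder and the mock embedder.
# PAD is pinned at id 0; the 20 standard amino acids and X (unknown) follow.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALPHABET <- c(AA20, "X")

#' Token vocabulary for local sequence windows
#'
#' A fixed bijection between window tokens and dense integer ids. The PAD
#' token (used beyond chain termini) always has id 0; the 20 standard amino
#' acids and `X` (unknown residue) have ids 1 to 21.
#'
#' @return A list with `tokens` (character vector indexed by id + 1),
#'   `ids` (named integer vector) and `size` (number of tokens).
#' @examples
#' v <- aa_vocabulary()
#' v$ids[["N"]]
#' @export
aa_vocabulary <- function() {
  tokens <- c("<PAD>", AA_ALPHABET)
  ids <- setNames(seq_along(tokens) - 1L, tokens)
  list(tokens = tokens, ids = ids, size = length(tokens))
}

# residue characters -> token ids (PAD = 0); unknown letters are an error
tokenize_residues <- function(chars) {
  ids <- match(chars, AA_ALPHABET)
  if (anyNA(ids)) {
    bad <- which(is.na(ids))[1]
    stop_deamid("illegal residue '", chars[bad], "'",
                class = "deamid_validation_error")
  }
  as.integer(ids)
}

decode_tokens <- function(ids) {
  stopifnot(all(ids >= 0), all(ids <= length(AA_ALPHABET)))
  paste(AA_ALPHABET[ids[ids > 0]], collapse = "")
}
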