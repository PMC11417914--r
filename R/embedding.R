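# Global per-residue contextual embeddings via a pluggable backend.
#
# The production backend for this workflow is a protein language model
# (per-residue hidden states, d = 1280 for the 650M-parameter ESM-2); any
# function mapping a sequence to an n x d matrix can be plugged in via
# make_custom_embedder(). The mock backend below reproduces the two
# properties the pipeline relies on -- determinism and context sensitivity
# -- without pretrained weights, so the whole package is testable offline.

MOCK_CTX <- 2L  # mock context half-width: vector depends on the +/-2 neighborhood

#' Create the deterministic mock embedding backend
#'
#' Each residue's vector is a seeded hash of its identity and its 5-residue
#' neighborhood: a fixed random basis vector is drawn for every
#' (offset, residue) pair and the per-residue embedding is the sum of the
#' five basis vectors selected by the neighborhood (chain termini use a
#' dedicated boundary symbol). Changing any neighbor changes the vector;
#' identical inputs give bitwise-identical output in any process. The sum
#' structure makes the mock informative (linear in the one-hot neighborhood)
#' rather than pure noise, which is what a contextual embedder is for.
#'
#' @param d embedding dimension (>= 1; default 32, small stand-in for 1280).
#' @param seed integer seed fixing the basis.
#' @param max_len maximum sequence length accepted by the backend.
#' @return An object of class `deamid_embedder`.
#' @examples
#' emb <- make_mock_embedder(d = 8, seed = 1)
#' m <- embed_chain(emb, list(molecule_id = "m", chain_id = "HC",
#'                            sequence = "QVNGS"))
#' dim(m$vectors)
#' @export
make_mock_embedder <- function(d = 32L, seed = 1L, max_len = 4096L) {
  assert_that(d >= 1, "embedding dimension must be >= 1",
              class = "deamid_validation_error")
  n_tok <- length(AA_ALPHABET) + 1L  # + boundary symbol
  n_off <- 2L * MOCK_CTX + 1L
  basis <- with_seed(seed, array(rnorm(d * n_tok * n_off), c(d, n_tok, n_off)))
  embed <- function(sequence) {
    chars <- strsplit(sequence, "")[[1]]
    ids <- tokenize_residues(chars)  # 1..21
    n <- length(ids)
    v <- matrix(0, d, n)
    for (off in -MOCK_CTX:MOCK_CTX) {
      shifted <- rep(n_tok, n)  # boundary token beyond termini
      src <- seq_len(n) + off
      in_range <- src >= 1 & src <= n
      shifted[in_range] <- ids[src[in_range]]
      v <- v + basis[, shifted, off + MOCK_CTX + 1L, drop = FALSE][, , 1]
    }
    t(v) / sqrt(n_off)
  }
  structure(list(name = sprintf("mock_d%d_s%d", d, seed),
                 d = as.integer(d), max_len = as.integer(max_len),
                 embed = embed, cache = new.env(parent = emptyenv())),
            class = "deamid_embedder")
}

#' Wrap an arbitrary embedding function as a backend
#'
#' Use this to plug in a real protein-language-model backend (for example
#' per-residue hidden states exported from an external ESM-2 run).
#'
#' @param embed_fn function taking a sequence string and returning an
#'   n x d numeric matrix (one row per residue).
#' @param d embedding dimension the function produces.
#' @param name backend identifier stored in model metadata.
#' @param max_len maximum sequence length the backend supports.
#' @return An object of class `deamid_embedder`.
#' @export
make_custom_embedder <- function(embed_fn, d, name, max_len = Inf) {
  assert_that(d >= 1, "embedding dimension must be >= 1",
              class = "deamid_validation_error")
  structure(list(name = name, d = as.integer(d), max_len = max_len,
                 embed = embed_fn, cache = new.env(parent = emptyenv())),
            class = "deamid_embedder")
}

# Rebuild a mock backend from the identifier stored in model metadata.
embedder_from_name <- function(name) {
  m <- regmatches(name, regexec("^mock_d([0-9]+)_s([0-9]+)$", name))[[1]]
  assert_that(length(m) == 3,
              "cannot reconstruct embedder '", name,
              "'; supply one via make_custom_embedder()",
              class = "deamid_validation_error")
  make_mock_embedder(d = as.integer(m[2]), seed = as.integer(m[3]))
}

#' Embed a full chain with a backend
#'
#' Returns one d-vector per residue, aligned 1:1 with sequence positions
#' (row i describes residue i). Results are cached per sequence within the
#' backend object.
#'
#' @param embedder a `deamid_embedder`.
#' @param chain a one-row chain data frame or list with `molecule_id`,
#'   `chain_id`, `sequence`.
#' @return A list of class `deamid_embedding` with fields `molecule_id`,
#'   `chain_id`, `embedder_name` and `vectors` (n x d matrix).
#' @export
embed_chain <- function(embedder, chain) {
  stopifnot(inherits(embedder, "deamid_embedder"))
  seq <- chain$sequence
  assert_that(nchar(seq) > 0, "empty sequence",
              class = "deamid_validation_error")
  assert_that(nchar(seq) <= embedder$max_len,
              "sequence of length ", nchar(seq),
              " exceeds backend capacity ", embedder$max_len,
              class = "deamid_capacity_error")
  v <- embedder$cache[[seq]]
  if (is.null(v)) {
    v <- embedder$embed(seq)
    assert_that(is.matrix(v) && nrow(v) == nchar(seq) && ncol(v) == embedder$d,
                "backend returned a ", nrow(v), " x ", ncol(v),
                " matrix for a length-", nchar(seq), " chain (d = ",
                embedder$d, ")", class = "deamid_validation_error")
    embedder$cache[[seq]] <- v
  }
  structure(list(molecule_id = chain$molecule_id %||% NA_character_,
                 chain_id = chain$chain_id %||% NA_character_,
                 embedder_name = embedder$name, vectors = v),
            class = "deamid_embedding")
}

#' Extract the embedding vector of one site
#'
#' @param embedding a `deamid_embedding` from [embed_chain()].
#' @param position 1-based residue index.
#' @return The 1 x d numeric vector of that residue, with provenance
#'   attributes `molecule_id`, `chain_id`, `position`.
#' @export
extract_site_vector <- function(embedding, position) {
  n <- nrow(embedding$vectors)
  assert_that(position >= 1 && position <= n,
              "position ", position, " out of range [1, ", n, "]",
              class = "deamid_index_error")
  structure(embedding$vectors[position, ],
            molecule_id = embedding$molecule_id,
            chain_id = embedding$chain_id,
            position = as.integer(position))
}
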