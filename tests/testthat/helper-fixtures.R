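# Shared fixtures: tiny chains, temp-file writers, fast training configs.

toy_chains <- function() {
  data.frame(
    molecule_id = c("mAbX", "mAbX", "mAbY"),
    chain_id = c("HC", "LC", "HC"),
    sequence = c("QVNGSANQSTNNKL", "DIQMTQSPNSLS", "EVQLVESGGGLVQ"),
    stringsAsFactors = FALSE)
}

write_toy_fasta <- function(chains = toy_chains()) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  write_fasta(chains, path)
  path
}

toy_timecourse <- function() {
  data.frame(
    molecule_id = c("mAbX", "mAbX", "mAbX"),
    chain_id = c("HC", "HC", "HC"),
    position = c(3L, 7L, 11L),
    residue = c("N", "N", "N"),
    pct_t0 = c(0.2, 0.1, NA), pct_1wk = c(1.5, 0.9, NA),
    pct_2wk = c(2.0, 1.8, NA), pct_4wk = c(4.1, 2.0, NA),
    pct_8wk = c(9.0, 2.4, NA),
    covered = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

# Fast config for unit tests (seconds, not minutes).
fast_config <- function(seed = 1L, window_size = 5L, ...) {
  benchmark_config(seed = seed, window_size = window_size,
                   max_epochs = 25L, patience = 5L, ...)
}

# Small synthetic world shared by model-level tests.
small_world <- function(n_molecules = 6L, seed = 7L, ...) {
  generate_synthetic(synthetic_spec(n_molecules = n_molecules, seed = seed,
                                    ...))
}

random_aa_string <- function(n) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y"), n, replace = TRUE), collapse = "")
}
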