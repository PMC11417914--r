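# Hot-spot labeling: convert measured time courses into binary labels and
# extent-regression targets.

#' Enumerate candidate deamidation sites of a chain
#'
#' @param chain either an amino-acid string or a one-row chain data frame.
#' @return A data frame with `position` (1-based, ascending) and `residue`
#'   for every N or Q in the sequence.
#' @examples
#' enumerate_candidate_sites("ANGQS")
#' @export
enumerate_candidate_sites <- function(chain) {
  seq <- if (is.character(chain) && length(chain) == 1) chain else chain$sequence
  chars <- strsplit(seq, "")[[1]]
  pos <- which(chars %in% c("N", "Q"))
  data.frame(position = as.integer(pos), residue = chars[pos],
             stringsAsFactors = FALSE)
}

#' Label sites as deamidation hot spots
#'
#' A site is labeled `active` when the measured deamidation extent rose by
#' strictly more than `threshold` percentage points over either of the two
#' early stress steps (week 0 to 1, or week 1 to 2). Absent extents are
#' treated as 0 for differencing, so sites without measurable deamidation
#' and uncovered sites are `inactive`. Extents at 2, 4 and 8 weeks are kept
#' as regression targets.
#'
#' @param timecourse time-course data frame (see [read_timecourse()]).
#' @param threshold percent increment that must be exceeded (default 1.0,
#'   strict inequality).
#' @return The input with an added `label` column (`"active"`/`"inactive"`).
#' @export
label_sites <- function(timecourse, threshold = 1.0) {
  z <- function(v) ifelse(is.na(v), 0, v)
  covered <- !is.na(timecourse$covered) & timecourse$covered
  d1 <- z(timecourse$pct_1wk) - z(timecourse$pct_t0)
  d2 <- z(timecourse$pct_2wk) - z(timecourse$pct_1wk)
  active <- covered & (d1 > threshold | d2 > threshold)
  timecourse$label <- ifelse(active, "active", "inactive")
  timecourse
}

#' Label a single site
#'
#' @param site a one-row time-course data frame or a list with fields
#'   `covered` and any of `pct_t0`, `pct_1wk`, `pct_2wk`, `pct_4wk`,
#'   `pct_8wk` (missing entries allowed).
#' @param threshold percent increment threshold (strict).
#' @return A list with `label` and `regression_targets` (named extents at
#'   2, 4 and 8 weeks; `NA` when absent).
#' @examples
#' label_site(list(covered = TRUE, pct_t0 = 0.2, pct_1wk = 1.5, pct_2wk = 2))
#' @export
label_site <- function(site, threshold = 1.0) {
  row <- as.data.frame(setNames(
    lapply(c("molecule_id", "chain_id", "position", "residue",
             names(TIMEPOINT_COLS), "covered"),
           function(f) site[[f]] %||% NA),
    c("molecule_id", "chain_id", "position", "residue",
      names(TIMEPOINT_COLS), "covered")), stringsAsFactors = FALSE)
  if (is.na(row$covered)) row$covered <- TRUE
  labeled <- label_sites(row, threshold)
  list(label = labeled$label,
       regression_targets = c(pct_2wk = labeled$pct_2wk,
                              pct_4wk = labeled$pct_4wk,
                              pct_8wk = labeled$pct_8wk))
}

#' Summarize the class balance of a labeled dataset
#'
#' @param labeled data frame with a `label` column.
#' @return A list of class `deamid_summary` with `n_total`, `n_active`,
#'   `n_inactive` and `active_fraction` (0 for an empty dataset).
#' @export
summarize_dataset <- function(labeled) {
  n_active <- sum(labeled$label == "active")
  n_total <- nrow(labeled)
  structure(list(n_total = n_total,
                 n_active = n_active,
                 n_inactive = n_total - n_active,
                 active_fraction = if (n_total > 0) n_active / n_total else 0),
            class = "deamid_summary")
}

#' @export
print.deamid_summary <- function(x, ...) {
  cat(sprintf("deamidation dataset: %d sites (%d active / %d inactive, %.1f%% active)\n",
              x$n_total, x$n_active, x$n_inactive, 100 * x$active_fraction))
  invisible(x)
}

#' Join chains with a time-course table into a labeled dataset
#'
#' Every N/Q site of every chain appears exactly once. Sites present in the
#' time-course table must resolve against the chains (position in range,
#' residue letter matching); sites absent from the table are treated as not
#' observed in the peptide map (`covered = FALSE`, hence inactive).
#'
#' @param chains chain data frame (see [read_fasta()]).
#' @param timecourse time-course data frame; may have zero rows.
#' @param threshold labeling threshold in percent (strict).
#' @return A labeled data frame (one row per candidate site).
#' @export
build_dataset <- function(chains, timecourse = NULL, threshold = 1.0) {
  sites <- do.call(rbind, lapply(seq_len(nrow(chains)), function(i) {
    s <- enumerate_candidate_sites(chains$sequence[i])
    if (nrow(s) == 0) return(NULL)
    cbind(data.frame(molecule_id = chains$molecule_id[i],
                     chain_id = chains$chain_id[i],
                     stringsAsFactors = FALSE), s)
  }))
  if (is.null(sites)) {
    sites <- data.frame(molecule_id = character(), chain_id = character(),
                        position = integer(), residue = character(),
                        stringsAsFactors = FALSE)
  }
  for (col in names(TIMEPOINT_COLS)) sites[[col]] <- NA_real_
  sites$covered <- FALSE
  if (!is.null(timecourse) && nrow(timecourse) > 0) {
    key_chain <- paste(chains$molecule_id, chains$chain_id, sep = "|")
    tc_chain <- match(paste(timecourse$molecule_id, timecourse$chain_id, sep = "|"),
                      key_chain)
    ok <- !is.na(tc_chain)
    len <- integer(nrow(timecourse))
    len[ok] <- nchar(chains$sequence[tc_chain[ok]])
    in_range <- ok & timecourse$position >= 1 & timecourse$position <= len
    res_at <- rep(NA_character_, nrow(timecourse))
    res_at[in_range] <- substring(chains$sequence[tc_chain[in_range]],
                                  timecourse$position[in_range],
                                  timecourse$position[in_range])
    bad <- !in_range | res_at != timecourse$residue
    bad[is.na(bad)] <- TRUE
    if (any(bad)) {
      rows <- which(bad)
      stop_deamid("unresolvable time-course rows (chain missing, position ",
                  "out of range, or residue mismatch): ",
                  paste(utils::head(rows, 10), collapse = ", "),
                  class = "deamid_validation_error")
    }
    skey <- paste(sites$molecule_id, sites$chain_id, sites$position)
    tkey <- paste(timecourse$molecule_id, timecourse$chain_id, timecourse$position)
    hit <- match(skey, tkey)
    found <- !is.na(hit)
    for (col in c(names(TIMEPOINT_COLS), "covered")) {
      sites[[col]][found] <- timecourse[[col]][hit[found]]
    }
  }
  label_sites(sites, threshold)
}
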