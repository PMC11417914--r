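# External representations: FASTA chains, time-course CSV tables, labeled
# datasets and prediction reports.

TIMEPOINT_COLS <- c(pct_t0 = 0, pct_1wk = 1, pct_2wk = 2, pct_4wk = 4, pct_8wk = 8)

validate_sequence <- function(seq, record = NULL) {
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad)) {
    stop_deamid("illegal residue '", chars[bad[1]], "' at position ", bad[1],
                if (!is.null(record)) paste0(" in record '", record, "'"),
                class = "deamid_validation_error")
  }
  invisible(seq)
}

new_chains <- function(molecule_id, chain_id, sequence) {
  df <- data.frame(molecule_id = as.character(molecule_id),
                   chain_id = as.character(chain_id),
                   sequence = as.character(sequence),
                   stringsAsFactors = FALSE)
  key <- paste(df$molecule_id, df$chain_id, sep = "|")
  assert_that(!anyDuplicated(key),
              "duplicate (molecule_id, chain_id): ",
              key[duplicated(key)][1],
              class = "deamid_validation_error")
  assert_that(all(nchar(df$sequence) > 0), "empty sequence",
              class = "deamid_validation_error")
  df
}

#' Read antibody chain sequences from a FASTA file
#'
#' Headers are interpreted as `moleculeID|chainID`; a header without `|`
#' gets chain id `"chain1"`. Sequences are upper-cased, terminal `*` stop
#' characters are stripped, and every residue must be one of the 20
#' standard amino acids or `X`.
#'
#' @param path path to a FASTA file.
#' @return A data frame with columns `molecule_id`, `chain_id`, `sequence`
#'   (one row per FASTA record; zero rows for an empty file).
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">mAbX|HC", "QVQLVQSG"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  assert_that(file.exists(path), "no such file: ", path,
              class = "deamid_io_error")
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (!length(nonblank)) {
    return(new_chains(character(), character(), character()))
  }
  if (!startsWith(lines[nonblank[1]], ">")) {
    stop_deamid("malformed FASTA: line ", nonblank[1],
                " is not a header", class = "deamid_parse_error")
  }
  hdr_idx <- which(startsWith(lines, ">"))
  records <- lapply(seq_along(hdr_idx), function(i) {
    from <- hdr_idx[i] + 1L
    to <- if (i < length(hdr_idx)) hdr_idx[i + 1] - 1L else length(lines)
    body <- if (from > to) "" else paste(trimws(lines[from:to]), collapse = "")
    header <- sub("^>\\s*", "", lines[hdr_idx[i]])
    header <- trimws(sub("\\s.*$", "", header))  # drop description
    if (header == "") {
      stop_deamid("malformed FASTA: empty header at line ", hdr_idx[i],
                  class = "deamid_parse_error")
    }
    seq <- toupper(gsub("\\*+$", "", body))
    if (nchar(seq) == 0) {
      stop_deamid("malformed FASTA: empty record '", header, "' at line ",
                  hdr_idx[i], class = "deamid_parse_error")
    }
    validate_sequence(seq, record = header)
    parts <- strsplit(header, "|", fixed = TRUE)[[1]]
    list(molecule_id = parts[1],
         chain_id = if (length(parts) >= 2 && nzchar(parts[2])) parts[2] else "chain1",
         sequence = seq)
  })
  new_chains(vapply(records, `[[`, "", "molecule_id"),
             vapply(records, `[[`, "", "chain_id"),
             vapply(records, `[[`, "", "sequence"))
}

#' Write chain sequences to a FASTA file
#'
#' @param chains data frame as returned by [read_fasta()].
#' @param path output path.
#' @param width line-wrap width for sequence bodies.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(chains, path, width = 60) {
  out <- unlist(lapply(seq_len(nrow(chains)), function(i) {
    seq <- chains$sequence[i]
    starts <- seq(1, nchar(seq), by = width)
    c(paste0(">", chains$molecule_id[i], "|", chains$chain_id[i]),
      substring(seq, starts, pmin(starts + width - 1, nchar(seq))))
  }))
  writeLines(out %||% character(), path)
  invisible(path)
}

#' Read a site-specific deamidation time-course table
#'
#' Expects a CSV with columns `molecule_id`, `chain_id`, `position`,
#' `residue`, `pct_t0`, `pct_1wk`, `pct_2wk`, `pct_4wk`, `pct_8wk`,
#' `covered`. Blank extent cells become `NA` (absent measurements);
#' `covered = FALSE` rows carry no extents.
#'
#' @param path path to the CSV file.
#' @return A data frame, one row per site.
#' @export
read_timecourse <- function(path) {
  assert_that(file.exists(path), "no such file: ", path,
              class = "deamid_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("molecule_id", "chain_id", "position", "residue",
                names(TIMEPOINT_COLS), "covered")
  missing <- setdiff(required, names(df))
  assert_that(length(missing) == 0, "missing columns: ",
              paste(missing, collapse = ", "), class = "deamid_parse_error")
  df <- df[required]
  df$position <- as.integer(df$position)
  df$covered <- as.logical(df$covered)
  validate_timecourse(df)
  df
}

validate_timecourse <- function(df) {
  bad <- which(!df$residue %in% c("N", "Q"))
  assert_that(length(bad) == 0, "residue not in {N, Q} at row ", bad[1],
              class = "deamid_validation_error")
  for (col in names(TIMEPOINT_COLS)) {
    v <- df[[col]]
    assert_that(!any(!is.na(v) & (v < 0 | v > 100)),
                "extent outside [0, 100] in column ", col,
                class = "deamid_validation_error")
  }
  uncov <- !is.na(df$covered) & !df$covered
  if (any(uncov)) {
    has_ext <- rowSums(!is.na(df[uncov, names(TIMEPOINT_COLS), drop = FALSE])) > 0
    assert_that(!any(has_ext), "covered = FALSE rows must carry no extents",
                class = "deamid_validation_error")
  }
  invisible(df)
}

#' Write a time-course table to CSV
#' @param df time-course data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(df, path) {
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

PREDICTION_COLS <- c("molecule", "chain", "position", "residue", "probability",
                     "predicted_label", "pred_extent_2wk", "pred_extent_4wk",
                     "pred_extent_8wk")

#' Write site predictions to CSV
#'
#' The header is always written, so an empty prediction set yields a
#' header-only file.
#'
#' @param predictions data frame with columns `molecule`, `chain`,
#'   `position`, `residue`, `probability`, `predicted_label`,
#'   `pred_extent_2wk`, `pred_extent_4wk`, `pred_extent_8wk`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  if (nrow(predictions) == 0) {
    predictions <- as.data.frame(setNames(rep(list(logical()),
                                              length(PREDICTION_COLS)),
                                          PREDICTION_COLS))
  }
  missing <- setdiff(PREDICTION_COLS, names(predictions))
  assert_that(length(missing) == 0, "missing prediction columns: ",
              paste(missing, collapse = ", "),
              class = "deamid_validation_error")
  write.csv(predictions[PREDICTION_COLS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a prediction report written by [write_predictions()]
#' @param path path to the CSV file.
#' @return A data frame of site predictions.
#' @export
read_predictions <- function(path) {
  assert_that(file.exists(path), "no such file: ", path,
              class = "deamid_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(position = "integer"))
  missing <- setdiff(PREDICTION_COLS, names(df))
  assert_that(length(missing) == 0, "missing prediction columns: ",
              paste(missing, collapse = ", "), class = "deamid_parse_error")
  df[PREDICTION_COLS]
}
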