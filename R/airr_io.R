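# AIRR-style rearrangement table I/O (tab-separated).

airr_mandatory <- c("sequence_id", "sequence", "v_call", "d_call", "j_call",
                    "c_call", "junction", "v_sequence_start", "v_sequence_end",
                    "j_sequence_start", "j_sequence_end", "duplicate_count")

#' Write an AIRR rearrangement table
#'
#' Tab-separated with AIRR column names; tool-specific columns are prefixed
#' `x_`. Empty strings are written as empty fields (not `NA`) so that a
#' write/read round trip is lossless.
#'
#' @param records rearrangement tibble (from [annotate_reads()] and friends).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_airr <- function(records, path) {
  missing_cols <- setdiff(airr_mandatory, names(records))
  if (length(missing_cols) > 0) {
    stop("missing mandatory AIRR columns: ",
         paste(missing_cols, collapse = ", "))
  }
  readr::write_tsv(records, path, na = "")
  invisible(path)
}

#' Read an AIRR rearrangement table
#'
#' Errors if mandatory columns are absent, naming them. Unknown extra columns
#' are preserved verbatim.
#'
#' @param path tab-separated AIRR file.
#' @return a tibble.
#' @export
read_airr <- function(path) {
  rec <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  missing_cols <- setdiff(airr_mandatory, names(rec))
  if (length(missing_cols) > 0) {
    stop("missing mandatory AIRR columns: ",
         paste(missing_cols, collapse = ", "))
  }
  int_cols <- intersect(
    c("v_sequence_start", "v_sequence_end", "j_sequence_start",
      "j_sequence_end", "duplicate_count", "x_v_mismatches",
      "x_v_germline_start", "x_v_germline_end", "x_v_nindel",
      "x_j_germline_start", "x_j_germline_end"),
    names(rec))
  for (cc in int_cols) {
    rec[[cc]] <- suppressWarnings(as.integer(rec[[cc]]))
  }
  for (cc in intersect(c("complete_vdj", "x_c_ambiguous"), names(rec))) {
    rec[[cc]] <- rec[[cc]] %in% c("TRUE", "T", "true")
  }
  rec
}
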