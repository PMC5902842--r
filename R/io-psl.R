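# PSL (BLAT) alignment tables: 21 tab-separated columns, optional
# "psLayout" header block. Coordinates in PSL are already 0-based
# half-open, so no conversion is needed.

PSL_COLS <- c(
  "matches", "mismatches", "rep_matches", "n_count",
  "q_num_insert", "q_base_insert", "t_num_insert", "t_base_insert",
  "strand", "query_id", "query_len", "query_start", "query_end",
  "target_id", "target_len", "target_start", "target_end",
  "block_count", "block_sizes", "q_starts", "t_starts"
)
PSL_INT_COLS <- setdiff(PSL_COLS, c("strand", "query_id", "target_id",
  "block_sizes", "q_starts", "t_starts"))

#' Read a PSL alignment file
#'
#' Accepts headered (`psLayout` block) or headerless PSL. Invalid rows are
#' rejected with their line number.
#'
#' @param file path to a PSL file, or a scalar of PSL text.
#' @return tibble with one row per alignment, standard PSL column names
#'   (`matches`, `query_id`, `query_len`, `block_sizes`, ...).
#' @export
read_psl <- function(file) {
  if (length(file) == 1 && grepl("[\t\n]", file)) {
    lines <- strsplit(file, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- readLines(file)
  }
  lineno <- seq_along(lines)
  # header block: psLayout line, column-name lines, dashes separator
  is_header <- grepl("^psLayout", lines) | grepl("^-+$", lines) |
    grepl("^(match\\b|\\s+match)", lines) | grepl("^\\s*(mis-|Q\\s)", lines) |
    !nzchar(trimws(lines))
  lines <- lines[!is_header]
  lineno <- lineno[!is_header]
  if (length(lines) == 0) return(empty_psl())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) != 21
  if (any(bad)) {
    abort(sprintf("PSL line %d has %d columns, expected 21",
      lineno[bad][1], lengths(fields)[bad][1]),
      class = "genesetqc_psl_error")
  }
  x <- as_tibble(do.call(rbind, fields), .name_repair = "minimal")
  names(x) <- PSL_COLS
  for (col in PSL_INT_COLS) x[[col]] <- as.integer(x[[col]])
  bad_counts <- x$matches + x$mismatches > x$query_len
  if (any(bad_counts)) {
    abort(sprintf("PSL line %d: matches + mismatches exceed query length",
      lineno[bad_counts][1]),
      class = "genesetqc_psl_error")
  }
  x
}

empty_psl <- function() {
  x <- as_tibble(setNames(rep(list(character()), 21), PSL_COLS))
  for (col in PSL_INT_COLS) x[[col]] <- integer()
  x
}

#' Write a PSL alignment table
#'
#' @param x tibble as returned by [read_psl()].
#' @param file output path.
#' @param header write the `psLayout` header block.
#' @return `file`, invisibly.
#' @export
write_psl <- function(x, file, header = FALSE) {
  con <- file(file, "w")
  on.exit(close(con))
  if (header) {
    writeLines(c("psLayout version 3", "",
      paste(c("match", "mis-", "rep.", "N's", "Q gapc", "Q gapb", "T gapc",
        "T gapb", "strand", "Q name", "Q size", "Q start", "Q end",
        "T name", "T size", "T start", "T end", "blocks", "blockSizes",
        "qStarts", "tStarts"), collapse = "\t"),
      paste(rep("-", 60), collapse = "")), con)
  }
  writeLines(do.call(paste, c(unname(as.list(x[, PSL_COLS])), sep = "\t")),
    con)
  invisible(file)
}
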