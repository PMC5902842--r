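# Per-base coverage tables in the `bedtools genomecov -d` dialect:
# seq_id <TAB> 1-based position <TAB> count, one row per base, zeros
# included. A coverage table in memory is a tibble with a `seq_id` column
# and a `counts` list-column of dense integer vectors (index 1 = first base).

#' Read a per-base coverage table
#'
#' @param file path to a 3-column TSV (`seq_id`, 1-based position, count),
#'   or a scalar of such text. Positions must be contiguous from 1 per
#'   sequence unless `seq_lengths` supplies the true lengths, in which case
#'   missing trailing positions are zero-filled.
#' @param seq_lengths optional named integer vector of sequence lengths.
#' @return tibble with columns `seq_id` and `counts` (list of integer
#'   vectors).
#' @export
read_coverage <- function(file, seq_lengths = NULL) {
  if (length(file) == 1 && grepl("\n", file)) {
    file <- I(file)
  }
  x <- readr::read_tsv(file, col_names = c("seq_id", "pos", "count"),
    col_types = "cii", progress = FALSE)
  if (nrow(x) == 0) {
    return(tibble(seq_id = character(), counts = list()))
  }
  if (any(x$count < 0)) {
    abort("negative coverage count", class = "genesetqc_coverage_error")
  }
  out <- x |>
    group_by(.data$seq_id) |>
    summarise(counts = {
      pos <- .data$pos
      cnt <- .data$count
      n_target <- if (!is.null(seq_lengths) && .data$seq_id[1] %in% names(seq_lengths)) {
        as.integer(seq_lengths[[.data$seq_id[1]]])
      } else {
        NA_integer_
      }
      if (is.na(n_target)) {
        if (!identical(pos, seq_along(pos))) {
          abort(sprintf(
            "non-contiguous positions for %s and no sequence length supplied",
            .data$seq_id[1]), class = "genesetqc_coverage_error")
        }
        list(cnt)
      } else {
        dense <- integer(n_target)
        if (any(pos < 1 | pos > n_target)) {
          abort(sprintf("position outside sequence %s", .data$seq_id[1]),
            class = "genesetqc_coverage_error")
        }
        dense[pos] <- cnt
        list(dense)
      }
    }, .groups = "drop")
  out[match(unique(x$seq_id), out$seq_id), ]
}

#' Write a per-base coverage table
#'
#' One row per base including zeros, matching `genomecov -d` output.
#'
#' @param x coverage tibble (`seq_id`, `counts` list-column).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_coverage <- function(x, file) {
  rows <- purrr::map2(x$seq_id, x$counts, function(id, cnt) {
    tibble(seq_id = id, pos = seq_along(cnt), count = as.integer(cnt))
  })
  readr::write_tsv(bind_rows(rows), file, col_names = FALSE, progress = FALSE)
  invisible(file)
}

#' Extract per-base counts for one interval
#'
#' @param track coverage tibble.
#' @param seq_id sequence name.
#' @param start,end 0-based half-open interval.
#' @return integer vector of length `end - start`.
#' @export
coverage_slice <- function(track, seq_id, start, end) {
  i <- match(seq_id, track$seq_id)
  if (is.na(i)) {
    abort(sprintf("sequence %s not present in coverage track", seq_id),
      class = "genesetqc_coverage_error")
  }
  cnt <- track$counts[[i]]
  if (end > length(cnt)) {
    abort(sprintf("interval [%d,%d) extends past end of %s (%d bases)",
      start, end, seq_id, length(cnt)), class = "genesetqc_coverage_error")
  }
  cnt[(start + 1L):end]
}
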