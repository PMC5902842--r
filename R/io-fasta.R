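# FASTA input/output. Sequences live in plain tibbles with columns
# id / description / residues / alphabet ("dna" or "protein"); the id is the
# first whitespace-delimited token of the header, the rest is description.
# Biostrings does the actual file parsing.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

guess_alphabet <- function(residues) {
  ifelse(
    vapply(
      strsplit(toupper(residues), ""),
      function(ch) all(ch %in% DNA_ALPHABET),
      logical(1)
    ),
    "dna", "protein"
  )
}

#' Build a sequence table
#'
#' @param id character vector of unique, non-empty identifiers.
#' @param residues character vector of sequences (uppercased on input).
#' @param description optional free-text descriptions.
#' @param alphabet "dna", "protein", or NULL to guess per record.
#' @return A tibble with columns `id`, `description`, `residues`, `alphabet`.
#' @export
seq_records <- function(id, residues, description = "", alphabet = NULL) {
  residues <- unname(toupper(residues))
  validate_seq_records(tibble(
    id = unname(as.character(id)),
    description = rep_len(as.character(description), length(id)),
    residues = residues,
    alphabet = alphabet %||% guess_alphabet(residues)
  ))
}

validate_seq_records <- function(x) {
  if (any(x$id == "" | is.na(x$id))) {
    abort("sequence records must have non-empty ids", class = "genesetqc_fasta_error")
  }
  dup <- x$id[duplicated(x$id)]
  if (length(dup) > 0) {
    abort(
      sprintf("duplicate sequence id(s): %s", paste(unique(dup), collapse = ", ")),
      class = "genesetqc_fasta_error"
    )
  }
  if (any(nchar(x$residues) == 0)) {
    abort(
      sprintf(
        "empty sequence for id(s): %s",
        paste(x$id[nchar(x$residues) == 0], collapse = ", ")
      ),
      class = "genesetqc_fasta_error"
    )
  }
  bad_dna <- x$alphabet == "dna" &
    grepl(sprintf("[^%s]", paste(DNA_ALPHABET, collapse = "")), x$residues)
  if (any(bad_dna)) {
    abort(
      sprintf(
        "non-ACGTN residue in dna record(s): %s",
        paste(x$id[bad_dna], collapse = ", ")
      ),
      class = "genesetqc_fasta_error"
    )
  }
  x
}

#' Read a FASTA file into a sequence table
#'
#' @param file path to a FASTA file, or a character scalar of FASTA text.
#' @param alphabet "dna", "protein", or NULL to guess per record.
#' @return A tibble with one row per record, in file order.
#' @export
read_fasta <- function(file, alphabet = NULL) {
  if (length(file) == 1 && grepl("\n", file)) {
    tmp <- withr::local_tempfile(fileext = ".fa")
    writeLines(file, tmp)
    file <- tmp
  }
  set <- Biostrings::readBStringSet(file)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(
    grepl("\\s", headers),
    sub("^\\S+\\s+", "", headers),
    ""
  )
  seq_records(id, as.character(set), description, alphabet = alphabet)
}

#' Write a sequence table to FASTA
#'
#' Round-trips with [read_fasta()]: `read_fasta(write_fasta(x, f))` equals `x`.
#'
#' @param x sequence table from [seq_records()]/[read_fasta()].
#' @param file output path.
#' @param width line-folding width in residues.
#' @return `file`, invisibly.
#' @export
write_fasta <- function(x, file, width = 60) {
  x <- validate_seq_records(x)
  set <- Biostrings::BStringSet(x$residues)
  names(set) <- ifelse(x$description == "", x$id, paste(x$id, x$description))
  Biostrings::writeXStringSet(set, file, width = width)
  invisible(file)
}
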