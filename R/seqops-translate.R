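# Translation under the standard genetic code. The codon table comes from
# Biostrings::GENETIC_CODE; codons containing N translate to X.

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(
    strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""), character(1)
  ))
}

codons_of <- function(dna) {
  n <- nchar(dna) %/% 3
  substring(dna, 3 * seq_len(n) - 2, 3 * seq_len(n))
}

translate_codons <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Translate a coding sequence
#'
#' @param cds a dna sequence string, or a one-row sequence table.
#' @param trim_final_stop drop a trailing `*`.
#' @param partial allow length not divisible by 3 (the 3' remainder is
#'   dropped with a warning).
#' @return protein string; an internal stop triggers a warning (attribute
#'   `internal_stop` is set to its codon index), never silent removal.
#' @export
translate_cds <- function(cds, trim_final_stop = TRUE, partial = FALSE) {
  if (is.data.frame(cds)) cds <- cds$residues[1]
  cds <- toupper(cds)
  if (nchar(cds) < 3) {
    abort("coding sequence shorter than one codon", class = "genesetqc_translate_error")
  }
  if (nchar(cds) %% 3 != 0) {
    if (!partial) {
      abort(sprintf("CDS length %d not divisible by 3", nchar(cds)),
        class = "genesetqc_translate_error")
    }
    warn(sprintf("dropping %d-base 3' remainder of partial CDS", nchar(cds) %% 3))
  }
  prot <- translate_codons(codons_of(cds))
  if (trim_final_stop) prot <- sub("\\*$", "", prot)
  internal <- regexpr("*", prot, fixed = TRUE)
  if (internal > 0 && internal < nchar(prot)) {
    warn(sprintf("internal stop codon at codon %d", internal))
    attr(prot, "internal_stop") <- as.integer(internal)
  }
  prot
}

#' Translate a sequence in all six frames
#'
#' Frames +1..+3 read the forward strand from offsets 0..2; frames -1..-3
#' read the reverse complement the same way. Stops are rendered as `*`.
#'
#' @param seq a dna sequence string, or a one-row sequence table.
#' @return tibble with columns `frame` (+1,+2,+3,-1,-2,-3) and `protein`.
#' @export
six_frame_translate <- function(seq) {
  if (is.data.frame(seq)) seq <- seq$residues[1]
  seq <- toupper(seq)
  if (nchar(seq) < 3) {
    abort("sequence shorter than one codon", class = "genesetqc_translate_error")
  }
  rc <- revcomp(seq)
  one <- function(s, off) {
    s <- substring(s, off + 1, nchar(s))
    translate_codons(codons_of(s))
  }
  tibble(
    frame = c(1L, 2L, 3L, -1L, -2L, -3L),
    protein = c(
      one(seq, 0), one(seq, 1), one(seq, 2),
      one(rc, 0), one(rc, 1), one(rc, 2)
    )
  )
}
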