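# Longest-ORF extraction over all six reading frames.

orf_no_result <- function() {
  tibble(found = FALSE, frame = NA_integer_, nt_start = NA_integer_,
    nt_end = NA_integer_, protein = NA_character_, partial3 = NA)
}

#' Find the longest open reading frame in a cDNA
#'
#' Scans all six frames for an ATG-initiated reading terminated by a stop
#' codon or by the end of the frame (then flagged `partial3`). The longest
#' protein wins; ties break by frame order (+1, +2, +3, -1, -2, -3), then
#' by leftmost start within the frame.
#'
#' @param cdna dna sequence string or one-row sequence table.
#' @param min_protein_len minimum protein length in residues (default 30).
#' @param require_start require an ATG start codon.
#' @return one-row tibble: `found`, `frame`, `nt_start`/`nt_end` (0-based
#'   half-open on the forward strand, including the stop codon when
#'   present), `protein`, `partial3`. `found = FALSE` when no qualifying
#'   ORF exists.
#' @export
longest_orf <- function(cdna, min_protein_len = 30, require_start = TRUE) {
  if (is.data.frame(cdna)) cdna <- cdna$residues[1]
  cdna <- toupper(cdna)
  L <- nchar(cdna)
  frames <- six_frame_translate(cdna)
  best <- orf_no_result()
  best_len <- min_protein_len - 1L
  for (k in seq_len(nrow(frames))) {
    f <- frames$frame[k]
    off <- abs(f) - 1L
    aa <- strsplit(frames$protein[k], "")[[1]]
    n_aa <- length(aa)
    if (n_aa == 0) next
    stops <- which(aa == "*")
    seg_starts <- c(1L, stops + 1L)
    seg_ends <- c(stops - 1L, n_aa)  # last codon before stop / frame end
    for (s in seq_along(seg_starts)) {
      a0 <- seg_starts[s]
      b <- seg_ends[s]
      if (b < a0) next
      has_stop <- s <= length(stops)
      if (require_start) {
        m <- which(aa[a0:b] == "M")
        if (length(m) == 0) next
        a <- a0 + m[1] - 1L
      } else {
        a <- a0
      }
      plen <- b - a + 1L
      if (plen <= best_len) next  # strict: earlier frame wins ties
      nt_a <- off + 3L * (a - 1L)
      nt_b <- off + 3L * b + (if (has_stop) 3L else 0L)
      if (f > 0) {
        span <- c(nt_a, nt_b)
      } else {
        span <- c(L - nt_b, L - nt_a)
      }
      best <- tibble(found = TRUE, frame = f, nt_start = span[1],
        nt_end = span[2], protein = paste(aa[a:b], collapse = ""),
        partial3 = !has_stop)
      best_len <- plen
    }
  }
  best
}
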