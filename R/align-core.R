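# Pairwise local alignment: scoring schemes, sequence encoding, the
# deterministic affine-gap Smith-Waterman backend (src/align.cpp), exact
# containment relations, and the percent-identity convention (matched
# residues over the full query length).

#' Protein alignment scoring (BLOSUM62, affine gaps 11/1)
#'
#' @param gap_open,gap_ext affine gap penalties; a gap of length L costs
#'   `gap_open + gap_ext * L`.
#' @param kmer seed word size used when deciding whether two sequences
#'   align at all (mirrors a BLAT-style seed requirement).
#' @return scoring scheme list.
#' @export
protein_scoring <- function(gap_open = 11, gap_ext = 1, kmer = 5) {
  mat <- get_blosum62()
  list(type = "protein", matrix = mat, alphabet = rownames(mat),
    unknown = "X", gap_open = gap_open, gap_ext = gap_ext, kmer = kmer)
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' DNA alignment scoring (match +1, mismatch -1, gaps 2/1)
#'
#' N scores 0 against everything.
#'
#' @inheritParams protein_scoring
#' @return scoring scheme list.
#' @export
dna_scoring <- function(gap_open = 2, gap_ext = 1, kmer = 11) {
  ab <- c("A", "C", "G", "T", "N")
  mat <- matrix(-1, 5, 5, dimnames = list(ab, ab))
  diag(mat) <- 1
  mat["N", ] <- 0
  mat[, "N"] <- 0
  list(type = "dna", matrix = mat, alphabet = ab, unknown = "N",
    gap_open = gap_open, gap_ext = gap_ext, kmer = kmer)
}

scoring_for <- function(residues) {
  if (all(guess_alphabet(residues) == "dna")) dna_scoring() else protein_scoring()
}

encode_seq <- function(residues, scoring) {
  chars <- strsplit(toupper(residues), "")
  unk <- match(scoring$unknown, scoring$alphabet)
  lapply(chars, function(ch) {
    idx <- match(ch, scoring$alphabet)
    idx[is.na(idx)] <- unk
    idx
  })
}

as_residues <- function(x) {
  if (is.data.frame(x)) x$residues else as.character(x)
}

as_ids <- function(x, default_prefix) {
  if (is.data.frame(x)) x$id else paste0(default_prefix, seq_along(x))
}

#' Optimal local alignment of two sequences
#'
#' Affine-gap Smith-Waterman with deterministic traceback (highest cell,
#' then lowest target index, then lowest query index; diagonal moves
#' preferred). `matches` counts identical aligned residue pairs.
#'
#' @param query,target sequence strings or one-row sequence tables.
#' @param scoring scheme from [protein_scoring()] / [dna_scoring()];
#'   guessed from the residues when NULL.
#' @return one-row tibble: `query_id`, `target_id`, `score`, `matches`,
#'   `query_len`, `target_len`, and 0-based half-open aligned spans
#'   `query_start`/`query_end`, `target_start`/`target_end`.
#' @export
local_align <- function(query, target, scoring = NULL) {
  q <- as_residues(query)[1]
  t <- as_residues(target)[1]
  scoring <- scoring %||% scoring_for(c(q, t))
  enc <- encode_seq(c(q, t), scoring)
  r <- cpp_local_align(enc[[1]], enc[[2]], scoring$matrix,
    scoring$gap_open, scoring$gap_ext)
  tibble(
    query_id = as_ids(query, "q")[1], target_id = as_ids(target, "t")[1],
    score = r$score, matches = r$matches,
    query_len = nchar(q), target_len = nchar(t),
    query_start = r$query_start, query_end = r$query_end,
    target_start = r$target_start, target_end = r$target_end
  )
}

#' Percent identity of an alignment
#'
#' 100 x matched residues over the chosen denominator length. The default
#' denominator is the full query length (the test-set convention: matched
#' residues divided by the total length of the query sequence).
#'
#' @param match alignment tibble with `matches`, `query_len`, `target_len`.
#' @param denominator "query_len" or "shorter_len".
#' @return numeric vector of percentages in `[0, 100]`, unrounded.
#' @export
percent_identity <- function(match, denominator = c("query_len", "shorter_len")) {
  denominator <- match.arg(denominator)
  den <- if (denominator == "query_len") {
    match$query_len
  } else {
    pmin(match$query_len, match$target_len)
  }
  stopifnot(all(den > 0))
  100 * match$matches / den
}

#' Exact sequence relation between two records
#'
#' Exact substring semantics: identical-and-equal-length takes precedence
#' over containment.
#'
#' @param query,target sequence strings or one-row sequence tables of the
#'   same alphabet.
#' @return one of "identical_equal_length", "query_contained_in_target",
#'   "target_contained_in_query", "none".
#' @export
exact_relation <- function(query, target) {
  q <- as_residues(query)[1]
  t <- as_residues(target)[1]
  if (guess_alphabet(q) != guess_alphabet(t)) {
    abort("exact_relation requires sequences of the same alphabet",
      class = "genesetqc_align_error")
  }
  if (q == t) return("identical_equal_length")
  if (grepl(q, t, fixed = TRUE)) return("query_contained_in_target")
  if (grepl(t, q, fixed = TRUE)) return("target_contained_in_query")
  "none"
}
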