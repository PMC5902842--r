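# Assembly-level utilities: Nx/Lx statistics, scaffold concatenation into a
# composite pseudo-chromosome, and identity-based deduplication.

#' Assembly length statistics
#'
#' Nx is the length of the sequence at which the cumulative
#' descending-sorted length first reaches x% of the total (cumulative >=,
#' ties kept in input order); Lx is its 1-based rank.
#'
#' @param x integer vector of sequence lengths, or a sequence table (then
#'   `percent_N` is also computed).
#' @return one-row tibble: `total_length`, `n_sequences`, `n50`, `l50`,
#'   `n90`, `l90`, `longest`, `percent_N` (NA when only lengths are given).
#' @export
assembly_stats <- function(x) {
  if (is.data.frame(x)) {
    lengths <- nchar(x$residues)
    pct_n <- round_half_up(100 * sum(stringr::str_count(x$residues, "N")) /
      sum(lengths), 2)
  } else {
    lengths <- as.integer(x)
    pct_n <- NA_real_
  }
  if (length(lengths) == 0) {
    abort("assembly_stats needs at least one sequence length",
      class = "genesetqc_stats_error")
  }
  ord <- order(lengths, decreasing = TRUE)  # stable: ties in input order
  sorted <- lengths[ord]
  cum <- cumsum(as.numeric(sorted))
  total <- cum[length(cum)]
  nx <- function(frac) {
    i <- which(cum >= frac * total)[1]
    c(n = sorted[i], l = i)
  }
  s50 <- nx(0.5)
  s90 <- nx(0.9)
  tibble(
    total_length = total, n_sequences = length(lengths),
    n50 = s50[["n"]], l50 = s50[["l"]],
    n90 = s90[["n"]], l90 = s90[["l"]],
    longest = sorted[1], percent_N = pct_n
  )
}

#' Concatenate scaffolds into a composite sequence
#'
#' Joins scaffolds in input order, separated by runs of N, and returns the
#' composite record together with a coordinate map that inverts losslessly.
#'
#' @param scaffolds sequence table.
#' @param spacer_n number of N bases between scaffolds (default 100).
#' @param id id for the composite record.
#' @return list with `record` (one-row sequence table; description records
#'   the spacer) and `map` (tibble `id`, `start`, `end`, 0-based half-open
#'   intervals on the composite).
#' @export
concatenate_scaffolds <- function(scaffolds, spacer_n = 100, id = "Chr30") {
  stopifnot(nrow(scaffolds) >= 1)
  lens <- nchar(scaffolds$residues)
  starts <- cumsum(dplyr::lag(lens + spacer_n, default = 0L))
  map <- tibble(id = scaffolds$id, start = as.integer(starts),
    end = as.integer(starts + lens))
  composite <- paste(scaffolds$residues,
    collapse = strrep("N", spacer_n))
  list(
    record = seq_records(id, composite,
      description = sprintf("composite of %d scaffolds, spacer_n=%d",
        nrow(scaffolds), spacer_n), alphabet = "dna"),
    map = map
  )
}

#' Extract scaffolds back out of a composite
#'
#' @param composite one-row sequence table from [concatenate_scaffolds()].
#' @param map coordinate map from [concatenate_scaffolds()].
#' @return sequence table of the original scaffolds.
#' @export
split_composite <- function(composite, map) {
  res <- substring(composite$residues[1], map$start + 1, map$end)
  seq_records(map$id, res, alphabet = "dna")
}

# identity between two sequences: matched residues of an end-gap-free
# global alignment divided by the shorter length
overlap_identity <- function(a, b) {
  cls <- if (guess_alphabet(a) == "dna" && guess_alphabet(b) == "dna") {
    "DNAString"
  } else {
    "AAString"
  }
  al <- Biostrings::pairwiseAlignment(
    methods::as(a, cls), methods::as(b, cls),
    type = "overlap"
  )
  Biostrings::nmatch(al) / min(nchar(a), nchar(b))
}

#' Remove near-duplicate sequences
#'
#' Greedy longest-first clustering: records are visited in decreasing
#' length order and join the first existing cluster whose representative
#' they match with identity (matched residues over the shorter length,
#' end-gap-free global alignment) above `threshold`; otherwise they found a
#' new cluster. Mirrors the `cd-hit-est` notion of redundancy removal.
#'
#' @param records sequence table.
#' @param threshold identity fraction above which a record is redundant
#'   (default 0.98; strictly-greater comparison).
#' @return list with `retained` (representatives, in decreasing length
#'   order) and `clusters` (tibble `id`, `representative`).
#' @export
dedup_by_identity <- function(records, threshold = 0.98) {
  stopifnot(nrow(records) >= 1)
  ord <- order(nchar(records$residues), decreasing = TRUE)
  reps <- integer(0)
  assign_to <- character(nrow(records))
  for (i in ord) {
    placed <- FALSE
    for (r in reps) {
      if (overlap_identity(records$residues[i], records$residues[r]) > threshold) {
        assign_to[i] <- records$id[r]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assign_to[i] <- records$id[i]
    }
  }
  list(
    retained = records[reps, ],
    clusters = tibble(id = records$id, representative = assign_to)
  )
}
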