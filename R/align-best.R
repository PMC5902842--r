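# Best-match selection across two sequence sets. A pair of sequences is
# considered alignable only when it shares at least one exact k-mer seed
# (k from the scoring scheme), echoing the seed requirement of the
# external aligners this replaces; seeded pairs are then aligned with the
# exact affine-gap backend.

seq_kmers <- function(residues, k) {
  n <- nchar(residues)
  if (n < k) return(residues)  # short sequences seed on themselves
  unique(substring(residues, 1:(n - k + 1), k:n))
}

kmer_candidate_pairs <- function(q_res, t_res, k) {
  q_res <- unname(q_res)
  t_res <- unname(t_res)
  qk <- bind_rows(purrr::map(seq_along(q_res), function(i) {
    tibble(kmer = seq_kmers(q_res[[i]], k), qi = i)
  }))
  tk <- bind_rows(purrr::map(seq_along(t_res), function(i) {
    tibble(kmer = seq_kmers(t_res[[i]], k), ti = i)
  }))
  # sequences shorter than k pair with everything
  short_q <- which(nchar(q_res) < k)
  short_t <- which(nchar(t_res) < k)
  pairs <- inner_join(qk, tk, by = "kmer", relationship = "many-to-many") |>
    distinct(.data$qi, .data$ti)
  extra <- bind_rows(
    tidyr::expand_grid(qi = short_q, ti = seq_along(t_res)),
    tidyr::expand_grid(qi = seq_along(q_res), ti = short_t)
  )
  distinct(bind_rows(pairs, extra), .data$qi, .data$ti)
}

# Align all seeded pairs; returns one row per pair with ids, matches and
# percent identity under both set directions.
align_candidate_pairs <- function(queries, targets, scoring = NULL,
                                  seed_filter = TRUE) {
  scoring <- scoring %||% scoring_for(c(queries$residues, targets$residues))
  if (seed_filter) {
    pairs <- kmer_candidate_pairs(queries$residues, targets$residues,
      scoring$kmer)
  } else {
    pairs <- tidyr::expand_grid(qi = seq_len(nrow(queries)),
      ti = seq_len(nrow(targets)))
  }
  if (nrow(pairs) == 0) {
    return(tibble(query_id = character(), target_id = character(),
      score = numeric(), matches = integer(), query_len = integer(),
      target_len = integer(), query_start = integer(), query_end = integer(),
      target_start = integer(), target_end = integer()))
  }
  qenc <- encode_seq(queries$residues, scoring)
  tenc <- encode_seq(targets$residues, scoring)
  m <- cpp_align_pairs(qenc, tenc, cbind(pairs$qi, pairs$ti),
    scoring$matrix, scoring$gap_open, scoring$gap_ext)
  tibble(
    query_id = queries$id[pairs$qi],
    target_id = targets$id[pairs$ti],
    score = m[, "score"], matches = as.integer(m[, "matches"]),
    query_len = nchar(queries$residues)[pairs$qi],
    target_len = nchar(targets$residues)[pairs$ti],
    query_start = as.integer(m[, "query_start"]),
    query_end = as.integer(m[, "query_end"]),
    target_start = as.integer(m[, "target_start"]),
    target_end = as.integer(m[, "target_end"])
  )
}

#' Best alignment target per query
#'
#' For every query the target maximising matched residues; ties break by
#' higher percent identity, then lexicographically smallest target id.
#' Queries with no seeded alignment at or above `min_report_identity` are
#' absent from the result.
#'
#' @param queries,targets sequence tables.
#' @param scoring scheme; guessed when NULL.
#' @param min_report_identity minimum percent identity (query-length
#'   denominator) for a best match to be reported; default 0 reports every
#'   seeded alignment.
#' @param seed_filter require a shared k-mer before aligning a pair; when
#'   FALSE every pair is aligned exhaustively.
#' @param alignments optional precomputed pair table from an earlier
#'   alignment round (or converted PSL input via [psl_as_matches()]), used
#'   verbatim instead of re-aligning.
#' @return tibble, one row per query with a match: `query_id`, `target_id`,
#'   `matches`, `query_len`, `target_len`, `percent_identity`, `score`.
#' @export
best_match_table <- function(queries, targets, scoring = NULL,
                             min_report_identity = 0, seed_filter = TRUE,
                             alignments = NULL) {
  al <- alignments %||% align_candidate_pairs(queries, targets, scoring,
    seed_filter)
  if (nrow(al) == 0) return(al[, c("query_id", "target_id", "matches",
    "query_len", "target_len")] |> mutate(percent_identity = numeric(0),
    score = numeric(0)))
  al$percent_identity <- percent_identity(al)
  al |>
    filter(.data$percent_identity >= min_report_identity) |>
    arrange(.data$query_id, desc(.data$matches),
      desc(.data$percent_identity), .data$target_id) |>
    group_by(.data$query_id) |>
    slice(1) |>
    ungroup() |>
    select("query_id", "target_id", "matches", "query_len", "target_len",
      "percent_identity", "score")
}

#' Convert PSL rows to the internal alignment-pair table
#'
#' The PSL `matches` field is used verbatim instead of re-aligning, for
#' bit-exact interoperability with externally computed alignments.
#'
#' @param psl tibble from [read_psl()].
#' @return pair table usable as `alignments` in [best_match_table()].
#' @export
psl_as_matches <- function(psl) {
  tibble(
    query_id = psl$query_id, target_id = psl$target_id,
    score = as.numeric(psl$matches), matches = psl$matches,
    query_len = psl$query_len, target_len = psl$target_len,
    query_start = psl$query_start, query_end = psl$query_end,
    target_start = psl$target_start, target_end = psl$target_end
  )
}

#' Reciprocal best matches between two sets
#'
#' A pair (q, t) is reciprocal-best iff t is q's best target and q is t's
#' best target.
#'
#' @param best_q2t,best_t2q best-match tables from [best_match_table()]
#'   run in the two directions.
#' @return tibble (`query_id`, `target_id`) sorted by `query_id`.
#' @export
reciprocal_best_matches <- function(best_q2t, best_t2q) {
  inner_join(
    select(best_q2t, "query_id", "target_id"),
    select(best_t2q, query_id2 = "query_id", target_id2 = "target_id"),
    by = c("target_id" = "query_id2")
  ) |>
    filter(.data$query_id == .data$target_id2) |>
    select("query_id", "target_id") |>
    arrange(.data$query_id)
}
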