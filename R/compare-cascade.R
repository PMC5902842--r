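# The classification cascade: every query model is tested first for exact
# protein relations against the target set, then for a best protein
# alignment, then for a best CDS alignment, and finally for whole-genome
# placement and its relation to target UTRs.

COMPARISON_CATEGORIES <- c(
  "identical_equal_length", "query_contained", "target_contained",
  "binned_match", "cds_only_match", "encapsulated_in_utr",
  "overlaps_5utr", "overlaps_3utr", "present_no_match",
  "missing_from_genome"
)

#' Cascade configuration
#'
#' @param min_protein_identity minimum percent identity (query-length
#'   denominator) for a protein alignment to count as a protein match
#'   (below it the cascade falls through to the CDS stage).
#' @param min_cds_identity minimum percent identity for a CDS alignment to
#'   count as a CDS-level match.
#' @param placement_min_identity,placement_min_coverage thresholds under
#'   which a query counts as placed on the genome (see
#'   [place_on_genome()]); failing both ways classifies it missing.
#' @return config list.
#' @export
cascade_config <- function(min_protein_identity = 30, min_cds_identity = 50,
                           placement_min_identity = 90,
                           placement_min_coverage = 0.5) {
  list(
    min_protein_identity = min_protein_identity,
    min_cds_identity = min_cds_identity,
    placement_min_identity = placement_min_identity,
    placement_min_coverage = placement_min_coverage
  )
}

#' Relation of a genomic span to a gene model's UTRs
#'
#' Encapsulated: the span lies inside the model's locus span and touches
#' no CDS segment (introns and UTRs both qualify). Overlapping a UTR: the
#' span intersects the strand-aware 5'/3' UTR and also extends outside the
#' locus or into the CDS; the 5' UTR takes precedence when both are hit.
#'
#' @param query_span list or one-row data frame with `seq_id`, `start`,
#'   `end` (0-based half-open).
#' @param target one row of a gene-model table.
#' @return "encapsulated_in_utr", "overlaps_5utr", "overlaps_3utr" or
#'   "none".
#' @export
utr_relation <- function(query_span, target) {
  if (query_span$seq_id[1] != target$seq_id[1]) return("none")
  q <- iv(query_span$start[1], query_span$end[1])
  cds <- target$cds[[1]]
  inside_locus <- q$start >= target$start[1] && q$end <= target$end[1]
  touches_cds <- iv_overlaps(q, cds)
  if (inside_locus && !touches_cds) return("encapsulated_in_utr")
  escapes <- !inside_locus || touches_cds
  if (iv_overlaps(q, target$utr5[[1]]) && escapes) return("overlaps_5utr")
  if (iv_overlaps(q, target$utr3[[1]]) && escapes) return("overlaps_3utr")
  "none"
}

# Pick the target model a placed query span should be judged against:
# the model overlapping the span whose locus contains the most of it;
# ties go to the smaller locus_id.
pick_utr_target <- function(query_span, models) {
  cand <- models[models$seq_id == query_span$seq_id[1], ]
  if (nrow(cand) == 0) return(NULL)
  q <- iv(query_span$start[1], query_span$end[1])
  ov <- vapply(seq_len(nrow(cand)), function(i) {
    iv_len(iv_intersect(q, iv(cand$start[i], cand$end[i])))
  }, numeric(1))
  cand <- cand[ov > 0, , drop = FALSE]
  ov <- ov[ov > 0]
  if (nrow(cand) == 0) return(NULL)
  cand[order(-ov, cand$locus_id)[1], ]
}

bin_of_identity <- function(identity) {
  stopifnot(all(is.na(identity) | (identity >= 0 & identity <= 100)))
  dplyr::case_when(
    is.na(identity) ~ "no_match",
    identity == 100 ~ "100",
    identity >= 95 ~ "95-99",
    identity >= 90 ~ "90-94",
    identity >= 85 ~ "85-89",
    identity >= 80 ~ "80-84",
    identity >= 75 ~ "75-79",
    identity >= 70 ~ "70-74",
    identity >= 65 ~ "65-69",
    identity >= 60 ~ "60-64",
    TRUE ~ "0-59"
  )
}

length_relation_of <- function(query_len, target_len) {
  dplyr::case_when(
    is.na(target_len) ~ "n/a",
    query_len == target_len ~ "equal",
    query_len < target_len ~ "query_shorter",
    TRUE ~ "query_longer"
  )
}

comparison_row <- function(query_id, category, best_target_id = NA_character_,
                           identity = NA_real_, bin = NULL,
                           length_relation = "n/a",
                           utr_rel = "none", seq_id = NA_character_,
                           genome_start = NA_integer_,
                           genome_end = NA_integer_) {
  tibble(
    query_id = query_id,
    category = category,
    best_target_id = best_target_id,
    percent_identity = identity,
    bin = bin %||% bin_of_identity(identity),
    length_relation = length_relation,
    utr_relation = utr_rel,
    seq_id = seq_id,
    genome_start = genome_start,
    genome_end = genome_end
  )
}

#' Classify one query model against a target gene set
#'
#' Runs the full cascade for a single query: exact protein relation, best
#' protein alignment, best CDS alignment, genome placement and UTR
#' relation. [compare_genesets()] runs the same decisions in bulk.
#'
#' @param query_protein,query_cds one-row sequence tables for the query.
#' @param target_set a [gene_set()].
#' @param placement one row of a [place_on_genome()] result for this query,
#'   NULL when no genome was searched, or a genome sequence table to
#'   search now.
#' @param config [cascade_config()].
#' @return one-row comparison tibble (`query_id`, `category`,
#'   `best_target_id`, `percent_identity`, `bin`, `length_relation`,
#'   `utr_relation`, genomic span).
#' @export
classify_model <- function(query_protein, query_cds, target_set,
                           placement = NULL, config = cascade_config()) {
  if (is.null(query_protein) && !is.null(query_cds) &&
    nchar(query_cds$residues[1]) >= 3) {
    abort("query has a CDS but no protein: run translation first",
      class = "genesetqc_compare_error")
  }
  if (is.data.frame(placement) && !"placed" %in% names(placement)) {
    # a genome sequence table: search it
    placement <- place_on_genome(query_cds, placement,
      config$placement_min_identity, config$placement_min_coverage)
  }
  qid <- query_protein$id[1]

  # stage 1: exact relations
  tp <- target_set$proteins
  rel <- vapply(tp$residues, function(t) {
    exact_relation(query_protein$residues[1], t)
  }, character(1))
  for (want in c("identical_equal_length", "query_contained_in_target",
    "target_contained_in_query")) {
    hit <- which(rel == want)
    if (length(hit) > 0) {
      ti <- hit[order(tp$id[hit])][1]
      identity <- 100 * min(nchar(tp$residues[ti]),
        nchar(query_protein$residues[1])) / nchar(query_protein$residues[1])
      cat <- switch(want,
        identical_equal_length = "identical_equal_length",
        query_contained_in_target = "query_contained",
        target_contained_in_query = "target_contained")
      return(comparison_row(qid, cat, tp$id[ti], identity,
        length_relation = length_relation_of(
          nchar(query_protein$residues[1]), nchar(tp$residues[ti]))))
    }
  }

  # stage 2: best protein alignment
  bm <- best_match_table(query_protein, tp)
  if (nrow(bm) > 0 && bm$percent_identity[1] >= config$min_protein_identity) {
    return(comparison_row(qid, "binned_match", bm$target_id[1],
      bm$percent_identity[1],
      length_relation = length_relation_of(bm$query_len[1], bm$target_len[1])))
  }

  # stage 3: best CDS alignment
  if (!is.null(target_set$cds) && !is.null(query_cds)) {
    bc <- best_match_table(query_cds, target_set$cds)
    if (nrow(bc) > 0 && bc$percent_identity[1] >= config$min_cds_identity) {
      return(comparison_row(qid, "cds_only_match", bc$target_id[1],
        bc$percent_identity[1], bin = "no_match"))
    }
  }

  # stages 4-5: genome placement
  if (is.null(placement)) {
    return(comparison_row(qid, "present_no_match"))
  }
  pl <- placement[placement$query_id == qid, , drop = FALSE]
  if (nrow(pl) == 0 || !pl$placed[1]) {
    return(comparison_row(qid, "missing_from_genome"))
  }
  span <- list(seq_id = pl$seq_id[1], start = pl$start[1], end = pl$end[1])
  target <- pick_utr_target(span, target_set$models)
  rel <- if (is.null(target)) "none" else utr_relation(span, target)
  cat <- if (rel == "none") "present_no_match" else rel
  comparison_row(qid, cat,
    best_target_id = if (rel == "none") NA_character_ else target$locus_id[1],
    utr_rel = rel, seq_id = span$seq_id,
    genome_start = as.integer(span$start), genome_end = as.integer(span$end))
}
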