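# Whole-gene-set comparison: the cascade applied to every query model,
# reciprocal best matches, the identity-bin table and headline fractions.

#' Bundle the pieces of one genotype's gene set
#'
#' @param proteins sequence table of predicted proteins (ids must match
#'   `cds` ids and, when given, model isoform ids).
#' @param cds optional sequence table of spliced coding sequences.
#' @param models optional gene-model tibble from [read_gff3()].
#' @param genome optional genome sequence table.
#' @return a `gene_set` list.
#' @export
gene_set <- function(proteins, cds = NULL, models = NULL, genome = NULL) {
  structure(
    list(proteins = proteins, cds = cds, models = models, genome = genome),
    class = "gene_set"
  )
}

IDENTITY_BIN_LEVELS <- c("0-59", "60-64", "65-69", "70-74", "75-79",
  "80-84", "85-89", "90-94", "95-99", "100", "no_match")

#' Count identities into the standard bins
#'
#' Bin edges: \[0,60), \[60,65), ..., \[95,100) and exactly 100; absent
#' identities (NA) count as `no_match`. Counts always sum to the input
#' length.
#'
#' @param identities numeric vector of percent identities in \[0,100\],
#'   NA for queries without a match.
#' @return tibble `bin` (ordered factor), `count`.
#' @export
bin_identities <- function(identities) {
  if (any(!is.na(identities) & (identities < 0 | identities > 100))) {
    abort("identity outside [0, 100]", class = "genesetqc_compare_error")
  }
  bins <- factor(bin_of_identity(identities), levels = IDENTITY_BIN_LEVELS)
  tibble(bin = factor(IDENTITY_BIN_LEVELS, levels = IDENTITY_BIN_LEVELS),
    count = as.integer(table(bins)))
}

#' Fraction of queries at or above an identity threshold
#'
#' 100 x (counts in bins whose lower edge is at or above the threshold)
#' over all queries including `no_match`, rounded half-up to one decimal.
#'
#' @param bin_table tibble from [bin_identities()] (or any tibble with
#'   `bin` and `count`).
#' @param threshold_bin lower edge of the first bin to include (default
#'   90).
#' @return percentage, one decimal.
#' @export
fraction_at_threshold <- function(bin_table, threshold_bin = 90) {
  n <- sum(bin_table$count)
  if (n == 0) {
    abort("empty bin table", class = "genesetqc_compare_error")
  }
  lower <- suppressWarnings(as.numeric(sub("-.*$", "", as.character(bin_table$bin))))
  hit <- !is.na(lower) & lower >= threshold_bin
  percent_of(sum(bin_table$count[hit]), n)
}

#' Compare a query gene set against a target gene set and genome
#'
#' Classifies every query model through the cascade (exact protein
#' relation, best protein alignment, best CDS alignment, genome placement
#' with UTR relation), computes reciprocal best protein matches in both
#' directions, and tabulates identity bins. Without a genome, queries that
#' reach the placement stage are classified `present_no_match`.
#'
#' @param query,target [gene_set()] objects (proteins required; `cds`
#'   enables the CDS stage; `target$models` and `genome` enable the
#'   placement/UTR stages).
#' @param genome genome sequence table of the target genotype; defaults to
#'   `target$genome`.
#' @param coverage optional coverage track on the target genome; placed
#'   queries without a protein match then also get a coarse support class
#'   over their placed span.
#' @param config [cascade_config()].
#' @return object of class `geneset_comparison`: `per_model` (one row per
#'   query), `bin_table`, `rbm`, `category_counts`, `n_queries`. See
#'   [tidy.geneset_comparison()], [glance.geneset_comparison()],
#'   [autoplot.geneset_comparison()].
#' @export
compare_genesets <- function(query, target, genome = NULL, coverage = NULL,
                             config = cascade_config()) {
  if (nrow(query$proteins) == 0) {
    abort("empty query set", class = "genesetqc_compare_error")
  }
  genome <- genome %||% target$genome
  qp <- query$proteins
  tp <- arrange(target$proteins, .data$id)
  n <- nrow(qp)

  # stage 1: exact relations, vectorised over queries
  exact_cat <- rep(NA_character_, n)
  exact_tid <- rep(NA_character_, n)
  ident_idx <- match(qp$residues, tp$residues)
  for (i in seq_len(n)) {
    if (!is.na(ident_idx[i]) &&
      nchar(tp$residues[ident_idx[i]]) == nchar(qp$residues[i])) {
      exact_cat[i] <- "identical_equal_length"
      exact_tid[i] <- tp$id[ident_idx[i]]
      next
    }
    inside <- stringr::str_detect(tp$residues, stringr::fixed(qp$residues[i])) &
      nchar(tp$residues) > nchar(qp$residues[i])
    if (any(inside)) {
      exact_cat[i] <- "query_contained"
      exact_tid[i] <- tp$id[which(inside)[1]]
      next
    }
    contains <- stringr::str_detect(qp$residues[i], stringr::fixed(tp$residues)) &
      nchar(tp$residues) < nchar(qp$residues[i])
    if (any(contains)) {
      exact_cat[i] <- "target_contained"
      exact_tid[i] <- tp$id[which(contains)[1]]
    }
  }

  # protein alignments once, reused for stage 2 and both RBM directions
  pairs <- align_candidate_pairs(qp, tp)
  best_q2t <- best_match_table(qp, tp, alignments = pairs)
  rev_pairs <- pairs |>
    rename(query_id = "target_id", target_id = "query_id",
      query_len = "target_len", target_len = "query_len",
      query_start = "target_start", query_end = "target_end",
      target_start = "query_start", target_end = "query_end")
  best_t2q <- best_match_table(tp, qp, alignments = rev_pairs)
  rbm <- reciprocal_best_matches(best_q2t, best_t2q)

  rows <- vector("list", n)
  unresolved <- integer(0)
  for (i in seq_len(n)) {
    qid <- qp$id[i]
    if (!is.na(exact_cat[i])) {
      ti <- match(exact_tid[i], tp$id)
      identity <- 100 * min(nchar(tp$residues[ti]), nchar(qp$residues[i])) /
        nchar(qp$residues[i])
      rows[[i]] <- comparison_row(qid, exact_cat[i], exact_tid[i], identity,
        length_relation = length_relation_of(nchar(qp$residues[i]),
          nchar(tp$residues[ti])))
      next
    }
    bm <- best_q2t[best_q2t$query_id == qid, ]
    if (nrow(bm) > 0 && bm$percent_identity[1] >= config$min_protein_identity) {
      rows[[i]] <- comparison_row(qid, "binned_match", bm$target_id[1],
        bm$percent_identity[1],
        length_relation = length_relation_of(bm$query_len[1], bm$target_len[1]))
      next
    }
    unresolved <- c(unresolved, i)
  }

  # stage 3: CDS alignments for unresolved queries
  cds_resolved <- integer(0)
  if (length(unresolved) > 0 && !is.null(query$cds) && !is.null(target$cds)) {
    qc <- query$cds[match(qp$id[unresolved], query$cds$id), ]
    bc <- best_match_table(qc, target$cds)
    for (i in unresolved) {
      b <- bc[bc$query_id == qp$id[i], ]
      if (nrow(b) > 0 && b$percent_identity[1] >= config$min_cds_identity) {
        rows[[i]] <- comparison_row(qp$id[i], "cds_only_match",
          b$target_id[1], b$percent_identity[1], bin = "no_match")
        cds_resolved <- c(cds_resolved, i)
      }
    }
    unresolved <- setdiff(unresolved, cds_resolved)
  }

  # stages 4-5: genome placement and UTR relation
  placements <- NULL
  if (length(unresolved) > 0) {
    if (is.null(genome) || is.null(query$cds)) {
      for (i in unresolved) {
        rows[[i]] <- comparison_row(qp$id[i], "present_no_match")
      }
    } else {
      qc <- query$cds[match(qp$id[unresolved], query$cds$id), ]
      placements <- place_on_genome(qc, genome,
        config$placement_min_identity, config$placement_min_coverage)
      for (i in unresolved) {
        pl <- placements[placements$query_id == qp$id[i], ]
        if (!pl$placed[1]) {
          rows[[i]] <- comparison_row(qp$id[i], "missing_from_genome")
          next
        }
        span <- list(seq_id = pl$seq_id[1], start = pl$start[1],
          end = pl$end[1])
        tm <- if (is.null(target$models)) NULL else {
          pick_utr_target(span, target$models)
        }
        rel <- if (is.null(tm)) "none" else utr_relation(span, tm)
        rows[[i]] <- comparison_row(qp$id[i],
          if (rel == "none") "present_no_match" else rel,
          best_target_id = if (rel == "none") NA_character_ else tm$locus_id[1],
          utr_rel = rel, seq_id = span$seq_id,
          genome_start = as.integer(span$start),
          genome_end = as.integer(span$end))
      }
    }
  }

  per_model <- bind_rows(rows)
  if (!is.null(coverage) && !is.null(placements)) {
    per_model <- left_join(per_model,
      span_support_class(per_model, coverage), by = "query_id")
  }
  bin_source <- ifelse(
    per_model$category %in% c("identical_equal_length", "query_contained",
      "target_contained", "binned_match"),
    per_model$percent_identity, NA_real_)
  structure(
    list(
      per_model = per_model,
      bin_table = bin_identities(bin_source),
      rbm = rbm,
      category_counts = per_model |>
        mutate(category = factor(.data$category,
          levels = COMPARISON_CATEGORIES)) |>
        dplyr::count(.data$category, .drop = FALSE, name = "count"),
      n_queries = n,
      config = config
    ),
    class = "geneset_comparison"
  )
}

# coarse support class over a placed genomic span (used when a coverage
# track accompanies the comparison)
span_support_class <- function(per_model, coverage) {
  placed <- per_model[!is.na(per_model$genome_start), ]
  if (nrow(placed) == 0) {
    return(tibble(query_id = character(), support_class = character()))
  }
  cls <- vapply(seq_len(nrow(placed)), function(i) {
    counts <- tryCatch(
      coverage_slice(coverage, placed$seq_id[i], placed$genome_start[i],
        placed$genome_end[i]),
      error = function(e) NULL)
    if (is.null(counts)) return(NA_character_)
    if (all(counts == 0)) {
      "no_coverage"
    } else if (mean(counts) < 5) {
      "low_coverage"
    } else {
      "supported"
    }
  }, character(1))
  tibble(query_id = placed$query_id, support_class = cls)
}

#' @describeIn compare_genesets per-model classification tibble.
#' @param x a `geneset_comparison`.
#' @param ... unused.
#' @export
tidy.geneset_comparison <- function(x, ...) x$per_model

#' @describeIn compare_genesets one-row summary: query count, identical
#'   count and fraction, reciprocal-best count, fraction at or above 90%
#'   identity.
#' @export
glance.geneset_comparison <- function(x, ...) {
  n_ident <- sum(x$per_model$category == "identical_equal_length")
  tibble(
    n_queries = x$n_queries,
    n_identical = n_ident,
    pct_identical = percent_of(n_ident, x$n_queries),
    n_rbm = nrow(x$rbm),
    pct_ge90 = fraction_at_threshold(x$bin_table, 90)
  )
}

#' @export
print.geneset_comparison <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Gene-set comparison: %d queries; %d identical (%.1f%%); %d reciprocal best matches; %.1f%% at >=90%% identity\n",
    g$n_queries, g$n_identical, g$pct_identical, g$n_rbm, g$pct_ge90))
  print(x$category_counts)
  invisible(x)
}

#' Plot a gene-set comparison
#'
#' Bar charts of the per-category counts and the identity-bin table.
#'
#' @param object a `geneset_comparison`.
#' @param which "categories" or "bins".
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.geneset_comparison <- function(object, which = c("categories", "bins"),
                                        ...) {
  which <- match.arg(which)
  if (which == "categories") {
    ggplot2::ggplot(object$category_counts,
      ggplot2::aes(x = .data$category, y = .data$count)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "query models")
  } else {
    ggplot2::ggplot(object$bin_table,
      ggplot2::aes(x = .data$bin, y = .data$count)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = "% identity bin", y = "query models")
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
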