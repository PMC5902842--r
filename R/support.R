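# Coverage-based evidence for gene models: per-exon coverage arrays, the
# 0/1 bitmap over CDS bases, the mean reads-per-base rule (< 5 is low
# coverage), and the quality tags that combine per-library support with
# protein homology (Q2/Q1/Q0 with F/P completeness and 5/3 truncation).

SUPPORT_CLASSES <- c("no_coverage", "unsupported_exon", "low_coverage",
  "supported")

#' Per-exon coverage profile of one gene model
#'
#' Coverage arrays are sliced per exon and per CDS segment in
#' transcription order; the bitmap and mean are computed over CDS bases
#' only (UTRs excluded).
#'
#' @param model one row of a gene-model tibble.
#' @param track coverage tibble from [read_coverage()].
#' @return one-row tibble: `model_id`, `cds_len`, `mean_reads_per_base`,
#'   `bitmap` (list of 0/1 integer vector over CDS bases),
#'   `exon_arrays`, `cds_arrays` (list of lists of integer vectors),
#'   `any_zero_cds_exon`.
#' @export
exon_coverage_profile <- function(model, track) {
  seq_id <- model$seq_id[1]
  if (!seq_id %in% track$seq_id) {
    abort(sprintf("sequence %s not present in coverage track", seq_id),
      class = "genesetqc_coverage_error")
  }
  slice_iv <- function(ivl) {
    lapply(seq_len(nrow(ivl)), function(j) {
      coverage_slice(track, seq_id, ivl$start[j], ivl$end[j])
    })
  }
  ex <- model$exons[[1]]
  cd <- model$cds[[1]]
  genomic_exon_arrays <- slice_iv(ex)
  genomic_cds_arrays <- slice_iv(cd)
  # transcription order: minus-strand models read right-to-left,
  # each array reversed
  to_tx <- function(arrays) {
    if (model$strand[1] == "-") rev(lapply(arrays, rev)) else arrays
  }
  exon_arrays <- to_tx(genomic_exon_arrays)
  cds_arrays <- to_tx(genomic_cds_arrays)
  cds_counts <- unlist(cds_arrays)
  # an exon "carries CDS" when it intersects a CDS segment; its support is
  # judged on its CDS bases
  per_exon_cds <- lapply(seq_len(nrow(ex)), function(j) {
    overlap <- iv_intersect(iv(ex$start[j], ex$end[j]), cd)
    unlist(slice_iv(overlap))
  })
  cds_bearing <- lengths(per_exon_cds) > 0
  tibble(
    model_id = model$isoform_id[1],
    cds_len = length(cds_counts),
    mean_reads_per_base = if (length(cds_counts) > 0) mean(cds_counts) else 0,
    bitmap = list(as.integer(cds_counts > 0)),
    exon_arrays = list(exon_arrays),
    cds_arrays = list(cds_arrays),
    any_zero_cds_exon = any(cds_bearing &
      vapply(per_exon_cds, function(x) all(x == 0), logical(1)))
  )
}

#' Classify RNA-seq support from a coverage profile
#'
#' Cascade: `no_coverage` when every CDS base is zero; else
#' `unsupported_exon` when any CDS-bearing exon has zero coverage over its
#' CDS bases; else `low_coverage` when the mean over CDS bases is below
#' `min_mean`; else `supported` (equality goes to `supported`).
#'
#' @param profile one-row tibble from [exon_coverage_profile()].
#' @param min_mean reads-per-base threshold (default 5).
#' @return one of `r paste(SUPPORT_CLASSES, collapse = ", ")`.
#' @export
classify_support <- function(profile, min_mean = 5) {
  if (all(profile$bitmap[[1]] == 0)) return("no_coverage")
  if (profile$any_zero_cds_exon[1]) return("unsupported_exon")
  if (profile$mean_reads_per_base[1] < min_mean) return("low_coverage")
  "supported"
}

#' Support classes for a whole gene-model table
#'
#' @param models gene-model tibble.
#' @param track coverage tibble (one library).
#' @param min_mean reads-per-base threshold (default 5).
#' @return tibble: `model_id`, `mean_reads_per_base`, `support_class`.
#' @export
profile_support <- function(models, track, min_mean = 5) {
  rows <- purrr::map(seq_len(nrow(models)), function(i) {
    p <- exon_coverage_profile(models[i, ], track)
    tibble(
      model_id = p$model_id,
      mean_reads_per_base = p$mean_reads_per_base,
      support_class = classify_support(p, min_mean)
    )
  })
  bind_rows(rows)
}

#' Quality tag from per-library support and homology
#'
#' Level 2 when supported in at least one library; level 1 when some
#' library shows coverage but none reaches supported; level 0 when no
#' library shows any coverage but protein homology exists. Completeness is
#' F when the homology covers at least `full_length_fraction` of the
#' reference protein, else P with the truncated end (5/3) appended —
#' rendering e.g. "2F", "1P3", "2P5".
#'
#' @param support_classes character vector, one support class per library.
#' @param ref_coverage_fraction fraction of the reference protein covered
#'   by the homology alignment, or NA when there is no homology.
#' @param missing_end "5", "3" or NA: which end the homology says is
#'   missing (used when partial).
#' @param full_length_fraction threshold for calling a model full length
#'   (default 0.9).
#' @return one-row tibble: `level`, `completeness`, `truncation`, `tag`;
#'   `tag` is `"no_evidence"` when there is neither coverage nor homology.
#' @export
assign_quality_tag <- function(support_classes, ref_coverage_fraction = NA,
                               missing_end = NA,
                               full_length_fraction = 0.9) {
  stopifnot(length(support_classes) >= 1)
  bad <- setdiff(support_classes, SUPPORT_CLASSES)
  if (length(bad) > 0) {
    abort(sprintf("unknown support class: %s", bad[1]),
      class = "genesetqc_support_error")
  }
  has_homology <- !is.na(ref_coverage_fraction)
  level <- if (any(support_classes == "supported")) {
    2L
  } else if (any(support_classes != "no_coverage")) {
    1L
  } else if (has_homology) {
    0L
  } else {
    return(tibble(level = NA_integer_, completeness = "none",
      truncation = "none", tag = "no_evidence"))
  }
  if (!has_homology) {
    completeness <- "none"
    truncation <- "none"
  } else if (ref_coverage_fraction >= full_length_fraction) {
    completeness <- "F"
    truncation <- "none"
  } else {
    completeness <- "P"
    truncation <- if (is.na(missing_end)) "none" else as.character(missing_end)
  }
  tag <- paste0(level,
    if (completeness != "none") completeness else "",
    if (truncation != "none") truncation else "")
  tibble(level = level, completeness = completeness, truncation = truncation,
    tag = tag)
}

#' Quality tags for a whole gene-model table across libraries
#'
#' @param models gene-model tibble.
#' @param tracks list of coverage tibbles, one per library.
#' @param homology optional tibble (`model_id`, `ref_coverage_fraction`,
#'   `missing_end`).
#' @param min_mean reads-per-base threshold (default 5).
#' @return tibble: `model_id`, per-library class columns
#'   (`class_lib1`, ...), `tag`.
#' @export
quality_tags <- function(models, tracks, homology = NULL, min_mean = 5) {
  per_lib <- purrr::imap(tracks, function(tr, k) {
    profile_support(models, tr, min_mean) |>
      select("model_id", "support_class") |>
      rename(!!paste0("class_lib", k) := "support_class")
  })
  wide <- purrr::reduce(per_lib, left_join, by = "model_id")
  class_cols <- grep("^class_lib", names(wide))
  tags <- purrr::map(seq_len(nrow(wide)), function(i) {
    h <- if (is.null(homology)) NULL else {
      homology[homology$model_id == wide$model_id[i], ]
    }
    assign_quality_tag(
      unlist(wide[i, class_cols]),
      ref_coverage_fraction = if (is.null(h) || nrow(h) == 0) NA else
        h$ref_coverage_fraction[1],
      missing_end = if (is.null(h) || nrow(h) == 0) NA else h$missing_end[1]
    )
  })
  dplyr::bind_cols(wide, bind_rows(tags))
}

#' Plot support-class composition
#'
#' @param support tibble with a `support_class` column (from
#'   [profile_support()]) or tag column from [quality_tags()].
#' @param var column to tabulate (default `support_class`).
#' @return a ggplot object.
#' @export
plot_support_classes <- function(support, var = "support_class") {
  counts <- dplyr::count(support, .data[[var]])
  ggplot2::ggplot(counts,
    ggplot2::aes(x = .data[[var]], y = .data$n)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = NULL, y = "gene models")
}
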