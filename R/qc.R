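# Structural annotation lint, stable locus naming, and tandem-duplicate
# site detection.

#' Lint rule thresholds
#'
#' @param min_intron introns shorter than this flag `small_intron`
#'   (default 15 bases; the shortest credible plant intron observed in
#'   curated sets is around 22 bases).
#' @param max_untranslated_exons more fully-untranslated exons than this
#'   flag `many_untranslated_exons` (default 3).
#' @return rules list.
#' @export
lint_rules <- function(min_intron = 15, max_untranslated_exons = 3) {
  list(min_intron = min_intron,
    max_untranslated_exons = max_untranslated_exons)
}

#' Extract the spliced sequence of intervals from a genome
#'
#' @param genome sequence table.
#' @param seq_id sequence name.
#' @param intervals interval tibble (0-based half-open), genomic order.
#' @param strand "+" or "-"; minus-strand results are reverse-complemented.
#' @return dna string.
#' @export
extract_spliced <- function(genome, seq_id, intervals, strand = "+") {
  i <- match(seq_id, genome$id)
  if (is.na(i)) {
    abort(sprintf("sequence %s not in genome", seq_id),
      class = "genesetqc_qc_error")
  }
  parts <- substring(genome$residues[i], intervals$start + 1, intervals$end)
  s <- paste(parts, collapse = "")
  if (strand == "-") revcomp(s) else s
}

#' Spliced CDS of one gene model
#'
#' @param model one row of a gene-model tibble.
#' @param genome sequence table.
#' @return dna string in transcription order.
#' @export
model_cds_sequence <- function(model, genome) {
  extract_spliced(genome, model$seq_id[1], model$cds[[1]], model$strand[1])
}

lint_flag <- function(model, rule, detail) {
  tibble(model_id = model$isoform_id[1], seq_id = model$seq_id[1],
    start = model$start[1], rule = rule, detail = detail)
}

#' Structural lint of gene models
#'
#' Flags small introns (< `min_intron` bases), models with more than
#' `max_untranslated_exons` fully untranslated exons and — when a genome
#' is supplied — sequence-level anomalies of the extracted CDS: missing
#' start codon, missing stop codon, internal stop, length not a multiple
#' of three. Partial models are exempt from the start/stop/frame rules on
#' the truncated side.
#'
#' @param models gene-model tibble.
#' @param genome optional sequence table (enables the sequence rules).
#' @param rules [lint_rules()].
#' @return tibble of flags (`model_id`, `seq_id`, `start`, `rule`,
#'   `detail`) sorted by (seq_id, start, rule); zero rows when clean.
#' @export
annotation_lint <- function(models, genome = NULL, rules = lint_rules()) {
  flags <- list()
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    ex <- m$exons[[1]]
    introns <- iv_gaps(ex, m$start[1], m$end[1])
    small <- introns$end - introns$start < rules$min_intron
    for (j in which(small)) {
      flags <- c(flags, list(lint_flag(m, "small_intron",
        sprintf("intron [%d,%d) of %d bases", introns$start[j],
          introns$end[j], introns$end[j] - introns$start[j]))))
    }
    cd <- m$cds[[1]]
    untranslated <- vapply(seq_len(nrow(ex)), function(j) {
      !iv_overlaps(iv(ex$start[j], ex$end[j]), cd)
    }, logical(1))
    if (sum(untranslated) > rules$max_untranslated_exons) {
      flags <- c(flags, list(lint_flag(m, "many_untranslated_exons",
        sprintf("%d untranslated exons", sum(untranslated)))))
    }
    if (!is.null(genome) && nrow(cd) > 0) {
      cds_seq <- model_cds_sequence(m, genome)
      L <- nchar(cds_seq)
      if (L %% 3 != 0 && !(m$partial5[1] || m$partial3[1])) {
        flags <- c(flags, list(lint_flag(m, "cds_not_multiple_of_3",
          sprintf("CDS length %d", L))))
      }
      if (!m$partial5[1] && substring(cds_seq, 1, 3) != "ATG") {
        flags <- c(flags, list(lint_flag(m, "missing_start",
          sprintf("CDS starts %s", substring(cds_seq, 1, 3)))))
      }
      n_codon <- L %/% 3
      if (n_codon >= 1) {
        codons <- codons_of(substring(cds_seq, 1, 3 * n_codon))
        aa <- Biostrings::GENETIC_CODE[codons]
        aa[is.na(aa)] <- "X"
        if (!m$partial3[1] && aa[n_codon] != "*") {
          flags <- c(flags, list(lint_flag(m, "missing_stop",
            sprintf("CDS ends %s", codons[n_codon]))))
        }
        internal <- which(aa[-n_codon] == "*")
        if (length(internal) > 0) {
          flags <- c(flags, list(lint_flag(m, "internal_stop",
            sprintf("stop at codon %d of %d", internal[1], n_codon))))
        }
      }
    }
  }
  if (length(flags) == 0) {
    return(tibble(model_id = character(), seq_id = character(),
      start = integer(), rule = character(), detail = character()))
  }
  bind_rows(flags) |> arrange(.data$seq_id, .data$start, .data$rule)
}

#' Assign stable locus names
#'
#' Names loci `<prefix><zero-padded counter>` in sorted genomic order,
#' with isoforms appended as ".1", ".2" in input order. The chromosome
#' location is returned as a separable descriptor, never embedded in the
#' name, so relocating a locus changes only its descriptor.
#'
#' @param models gene-model tibble sorted by (seq_id, start).
#' @param prefix name prefix (default "Acc").
#' @param start_index first counter value (default 1).
#' @param width zero-padding width (default 5).
#' @return tibble: `locus_id`, `isoform_id`, `locus_name`, `isoform_name`,
#'   `descriptor` (`seq_id:start-end`, 1-based inclusive display).
#' @export
name_genes <- function(models, prefix = "Acc", start_index = 1, width = 5) {
  loci <- unique(models$locus_id)
  idx <- start_index + seq_along(loci) - 1
  if (any(idx > 10^width - 1)) {
    abort(sprintf("locus counter exceeds width %d", width),
      class = "genesetqc_qc_error")
  }
  locus_names <- setNames(sprintf(paste0(prefix, "%0", width, "d"), idx), loci)
  models |>
    group_by(.data$locus_id) |>
    mutate(isoform_rank = row_number()) |>
    ungroup() |>
    mutate(
      locus_name = unname(locus_names[.data$locus_id]),
      isoform_name = paste0(.data$locus_name, ".", .data$isoform_rank),
      descriptor = sprintf("%s:%d-%d", .data$seq_id, .data$start + 1L,
        .data$end)
    ) |>
    select("locus_id", "isoform_id", "locus_name", "isoform_name",
      "descriptor")
}

#' Find tandemly duplicated gene sites
#'
#' Single-linkage clustering of loci on the same sequence whose genomic
#' ranks differ by at most `max_intervening + 1` and whose proteins align
#' with identity (matched residues over the shorter length) at or above
#' `min_identity`. Sites are maximal clusters of two or more loci; no
#' locus belongs to two sites.
#'
#' @param models gene-model tibble (one representative isoform per locus:
#'   the longest-protein isoform is chosen automatically).
#' @param proteins sequence table keyed by isoform id.
#' @param min_identity identity fraction threshold (default 0.9).
#' @param max_intervening maximum number of genes allowed between two
#'   members (default 1).
#' @return tibble: `seq_id`, `start`, `end`, `n_members`, `members`
#'   (list of locus ids in genomic order).
#' @export
find_tandem_duplicates <- function(models, proteins, min_identity = 0.9,
                                   max_intervening = 1) {
  prot_len <- setNames(nchar(proteins$residues), proteins$id)
  reps <- models |>
    mutate(plen = unname(prot_len[.data$isoform_id])) |>
    group_by(.data$locus_id) |>
    arrange(desc(.data$plen), .data$isoform_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$seq_id, .data$start)
  n <- nrow(reps)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  scoring <- protein_scoring()
  for (sid in unique(reps$seq_id)) {
    on_seq <- which(reps$seq_id == sid)
    for (a in seq_along(on_seq)) {
      for (b in seq_len(min(max_intervening + 1, length(on_seq) - a))) {
        i <- on_seq[a]
        j <- on_seq[a + b]
        pi <- proteins$residues[match(reps$isoform_id[i], proteins$id)]
        pj <- proteins$residues[match(reps$isoform_id[j], proteins$id)]
        al <- local_align(seq_records("a", pi), seq_records("b", pj), scoring)
        ident <- al$matches / min(nchar(pi), nchar(pj))
        if (ident >= min_identity) {
          parent[find(i)] <- find(j)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  sites <- list()
  for (r in unique(root)) {
    members <- which(root == r)
    if (length(members) < 2) next
    members <- members[order(reps$start[members])]
    sites <- c(sites, list(tibble(
      seq_id = reps$seq_id[members[1]],
      start = min(reps$start[members]),
      end = max(reps$end[members]),
      n_members = length(members),
      members = list(reps$locus_id[members])
    )))
  }
  if (length(sites) == 0) {
    return(tibble(seq_id = character(), start = integer(), end = integer(),
      n_members = integer(), members = list()))
  }
  bind_rows(sites) |> arrange(.data$seq_id, .data$start)
}
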