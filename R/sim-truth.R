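# Reference ("truth") gene-set generation: non-overlapping multi-exon
# genes with ATG..stop coding sequences, UTRs on both ends, introns of at
# least 22 bases, placed on a random-background genome. Gene geometry is
# co-designed with the planted comparison categories: genes destined to
# host a relocated CDS get a long 3' UTR, and genes destined to straddle
# a UTR boundary get generous intergenic room.

RELOC_CATEGORIES <- c("encapsulated_in_utr", "overlaps_5utr", "overlaps_3utr")

#' Generate the reference gene set and genome
#'
#' @param config [sim_config()].
#' @return list: `genome` (sequence table), `models` (gene-model tibble),
#'   `cds`, `proteins` (sequence tables keyed by isoform id), `truth`
#'   (one row per gene: planted category, planted identity bin and target,
#'   relocation host).
#' @export
generate_truth_set <- function(config = sim_config()) {
  with_seed(child_seed(config$seed, 1), generate_truth_set_impl(config))
}

generate_truth_set_impl <- function(config) {
  n <- config$n_genes
  if (n == 0) {
    glen <- config$genome_len %||% 10000
    genome <- seq_records(
      sprintf("chr%02d", seq_len(config$n_seqs)),
      vapply(seq_len(config$n_seqs), function(i) {
        random_dna(ceiling(glen / config$n_seqs), config$gc)
      }, character(1))
    )
    return(list(genome = genome, models = empty_gene_models(),
      cds = seq_records(character(0), character(0))[0, ],
      proteins = seq_records(character(0), character(0))[0, ],
      truth = tibble(gene_id = character(), isoform_id = character(),
        seq_id = character(), strand = character(), category = character(),
        planted_bin = character(), target_identity = numeric(),
        host_id = character())))
  }

  cats <- rep(names(config$category_mix), mix_counts(config$category_mix, n))
  cats <- sample(cats)
  reloc <- which(cats %in% RELOC_CATEGORIES)
  ident <- which(cats == "identical_equal_length")
  n_encap <- sum(cats == "encapsulated_in_utr")
  n_o5 <- sum(cats == "overlaps_5utr")
  n_o3 <- sum(cats == "overlaps_3utr")
  if (length(ident) < length(reloc)) {
    abort(sprintf(
      "category_mix incompatible with n_genes: %d relocations need %d identical hosts, have %d",
      length(reloc), length(reloc), length(ident)),
      class = "genesetqc_sim_error")
  }
  hosts_encap <- ident[seq_len(n_encap)]
  hosts_o5 <- ident[n_encap + seq_len(n_o5)]
  hosts_o3 <- ident[n_encap + n_o5 + seq_len(n_o3)]
  overlap_host <- seq_len(n) %in% c(hosts_o5, hosts_o3)
  host_of <- integer(n)  # relocated gene -> host gene index
  host_of[which(cats == "encapsulated_in_utr")] <- hosts_encap
  host_of[which(cats == "overlaps_5utr")] <- hosts_o5
  host_of[which(cats == "overlaps_3utr")] <- hosts_o3

  # planted identity bins for binned genes
  planted_bin <- rep(NA_character_, n)
  binned <- which(cats == "binned_match")
  if (length(binned) > 0) {
    bins <- rep(names(config$bin_mix),
      mix_counts(config$bin_mix, length(binned)))
    planted_bin[binned] <- sample(bins)
  }

  # per-gene geometry
  genes <- vector("list", n)
  for (i in seq_len(n)) {
    cds_codons <- if (i %in% reloc) 101L else sample(100:250, 1)
    cds_len <- 3L * cds_codons
    utr5 <- sample(40:120, 1)
    utr3 <- if (i %in% hosts_encap) 700L else sample(120:450, 1)
    max_exons <- max(1L, min(6L, cds_len %/% 100L))
    n_exons <- sample(seq_len(max_exons), 1)
    # CDS split into n_exons segments, each >= 100 bases
    extra <- cds_len - 100L * n_exons
    cuts <- if (n_exons > 1) sort(sample(0:extra, n_exons - 1, replace = TRUE)) else integer(0)
    seg <- 100L + diff(c(0L, cuts, extra))
    introns <- if (n_exons > 1) sample(22:80, n_exons - 1, replace = TRUE) else integer(0)
    cds_seq <- random_cds(cds_codons)
    transcript <- paste0(random_dna(utr5, config$gc), cds_seq,
      random_dna(utr3, config$gc))
    # exon intervals in transcript coordinates: first exon carries the
    # whole 5' UTR, last the whole 3' UTR, cuts fall inside the CDS
    tx_bounds <- utr5 + cumsum(seg[-n_exons])
    ex_tx_start <- c(0L, tx_bounds)
    ex_tx_end <- c(tx_bounds, nchar(transcript))
    # genomic assembly with introns
    pieces <- character(0)
    gs <- integer(n_exons)
    ge <- integer(n_exons)
    cursor <- 0L
    for (e in seq_len(n_exons)) {
      exon_seq <- substring(transcript, ex_tx_start[e] + 1, ex_tx_end[e])
      gs[e] <- cursor
      ge[e] <- cursor + nchar(exon_seq)
      cursor <- ge[e]
      pieces <- c(pieces, exon_seq)
      if (e < n_exons) {
        pieces <- c(pieces, random_dna(introns[e], config$gc))
        cursor <- cursor + introns[e]
      }
    }
    gseq <- paste(pieces, collapse = "")
    # CDS genomic intervals: CDS occupies [utr5, utr5 + cds_len) in
    # transcript coords; intersect with exon transcript spans and shift
    cds_iv_list <- lapply(seq_len(n_exons), function(e) {
      lo <- max(ex_tx_start[e], utr5)
      hi <- min(ex_tx_end[e], utr5 + cds_len)
      if (hi <= lo) return(NULL)
      c(gs[e] + (lo - ex_tx_start[e]), gs[e] + (hi - ex_tx_start[e]))
    })
    cds_iv_list <- cds_iv_list[!vapply(cds_iv_list, is.null, logical(1))]
    cds_mat <- do.call(rbind, cds_iv_list)
    strand <- sample(c("+", "-"), 1)
    glen <- nchar(gseq)
    if (strand == "-") {
      gseq <- revcomp(gseq)
      flip <- function(s, e) cbind(glen - e, glen - s)
      exm <- flip(gs, ge)
      exm <- exm[order(exm[, 1]), , drop = FALSE]
      cdm <- flip(cds_mat[, 1], cds_mat[, 2])
      cdm <- cdm[order(cdm[, 1]), , drop = FALSE]
    } else {
      exm <- cbind(gs, ge)
      cdm <- cds_mat
    }
    genes[[i]] <- list(seq = gseq, exons = exm, cds = cdm, strand = strand,
      cds_seq = cds_seq, utr5 = utr5, utr3 = utr3)
  }

  # layout: contiguous blocks of genes per chromosome
  chr_of <- sort(rep_len(seq_len(config$n_seqs), n))
  chrom_seqs <- character(config$n_seqs)
  offsets <- integer(n)
  for (s in seq_len(config$n_seqs)) {
    on_chr <- which(chr_of == s)
    parts <- character(0)
    cursor <- 0L
    prev_overlap_host <- FALSE
    for (i in on_chr) {
      lo <- if (overlap_host[i] || prev_overlap_host) 500L else 300L
      gap <- sample(lo:800, 1)
      parts <- c(parts, random_dna(gap, config$gc))
      cursor <- cursor + gap
      offsets[i] <- cursor
      parts <- c(parts, genes[[i]]$seq)
      cursor <- cursor + nchar(genes[[i]]$seq)
      prev_overlap_host <- overlap_host[i]
    }
    parts <- c(parts, random_dna(500L, config$gc))
    chrom_seqs[s] <- paste(parts, collapse = "")
  }
  required <- sum(nchar(chrom_seqs))
  if (!is.null(config$genome_len)) {
    if (config$genome_len < required) {
      abort(sprintf("genome too small for %d genes: need at least %d bases",
        n, required), class = "genesetqc_sim_error")
    }
    pad <- config$genome_len - required
    per <- mix_counts(rep(1 / config$n_seqs, config$n_seqs), pad)
    for (s in seq_len(config$n_seqs)) {
      if (per[s] > 0) {
        chrom_seqs[s] <- paste0(chrom_seqs[s], random_dna(per[s], config$gc))
      }
    }
  }
  chr_ids <- sprintf("chr%02d", seq_len(config$n_seqs))
  genome <- seq_records(chr_ids, chrom_seqs, alphabet = "dna")

  locus_ids <- sprintf("gA%04d", seq_len(n))
  models <- bind_rows(lapply(seq_len(n), function(i) {
    g <- genes[[i]]
    off <- offsets[i]
    gene_model(
      seq_id = chr_ids[chr_of[i]],
      locus_id = locus_ids[i], strand = g$strand,
      exons = iv(g$exons[, 1] + off, g$exons[, 2] + off),
      cds = iv(g$cds[, 1] + off, g$cds[, 2] + off)
    )
  })) |> arrange(.data$seq_id, .data$start)

  cds_tbl <- seq_records(paste0(locus_ids, ".1"),
    vapply(genes, `[[`, character(1), "cds_seq"), alphabet = "dna")
  prot_tbl <- seq_records(paste0(locus_ids, ".1"),
    vapply(genes, function(g) {
      as.character(translate_cds(g$cds_seq))
    }, character(1)), alphabet = "protein")

  truth <- tibble(
    gene_id = locus_ids,
    isoform_id = paste0(locus_ids, ".1"),
    seq_id = chr_ids[chr_of],
    strand = vapply(genes, `[[`, character(1), "strand"),
    category = cats,
    planted_bin = planted_bin,
    target_identity = unname(BIN_TARGETS[planted_bin]),
    host_id = ifelse(host_of > 0, locus_ids[pmax(host_of, 1)], NA_character_)
  )

  list(genome = genome, models = models, cds = cds_tbl,
    proteins = prot_tbl, truth = truth)
}
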