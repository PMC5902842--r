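# GFF3 gene models. A gene-model table has one row per isoform:
#   seq_id, locus_id, isoform_id, strand ("+"/"-"),
#   start, end            -- locus span, 0-based half-open
#   exons, cds            -- list-columns of interval tibbles (start, end)
#   utr5, utr3            -- derived strand-aware UTR intervals (exon - CDS);
#                            always re-derived, never read from UTR features
#   partial5, partial3    -- logical truncation flags
# GFF3 carries 1-based inclusive coordinates; conversion happens only here.

#' Build one gene model row
#'
#' @param seq_id chromosome/scaffold id.
#' @param locus_id,isoform_id identifiers; isoform defaults to `<locus>.1`.
#' @param strand "+" or "-".
#' @param exons,cds data frames with 0-based half-open `start`, `end` columns.
#' @param partial5,partial3 logical truncation flags.
#' @return a one-row gene-model tibble.
#' @export
gene_model <- function(seq_id, locus_id, strand, exons, cds,
                       isoform_id = paste0(locus_id, ".1"),
                       partial5 = FALSE, partial3 = FALSE) {
  exons <- iv_sort(iv(exons$start, exons$end))
  cds <- iv_sort(iv(cds$start, cds$end))
  m <- tibble(
    seq_id = seq_id, locus_id = locus_id, isoform_id = isoform_id,
    strand = strand,
    start = min(exons$start), end = max(exons$end),
    exons = list(exons), cds = list(cds),
    utr5 = list(iv()), utr3 = list(iv()),
    partial5 = partial5, partial3 = partial3
  )
  derive_utrs(validate_gene_models(m))
}

#' Validate a gene-model table's structural invariants
#'
#' Checks interval ordering, exon containment of CDS segments and minimum
#' CDS length; raises a typed error describing the first violation.
#'
#' @param models gene-model tibble.
#' @return `models`, invisibly usable.
#' @export
validate_gene_models <- function(models) {
  for (i in seq_len(nrow(models))) {
    id <- models$isoform_id[i]
    ex <- models$exons[[i]]
    cd <- models$cds[[i]]
    stopifnot_intervals(ex, paste("exon of", id))
    stopifnot_intervals(cd, paste("CDS of", id))
    if (nrow(ex) == 0) {
      abort(sprintf("model %s has no exons", id), class = "genesetqc_gff3_error")
    }
    if (any(diff(c(rbind(ex$start, ex$end))) < 0)) {
      abort(sprintf("overlapping or unsorted exons in %s", id),
        class = "genesetqc_gff3_error")
    }
    if (min(ex$start) < models$start[i] || max(ex$end) > models$end[i]) {
      abort(sprintf("exon outside locus span in %s", id),
        class = "genesetqc_gff3_error")
    }
    if (nrow(cd) > 0 && !iv_within(cd, ex)) {
      abort(sprintf("CDS outside exon in model %s", id),
        class = "genesetqc_gff3_error")
    }
    if (iv_len(cd) < 3 && !(models$partial5[i] || models$partial3[i])) {
      abort(sprintf("CDS of %s shorter than one codon and not flagged partial", id),
        class = "genesetqc_gff3_error")
    }
  }
  models
}

# UTR intervals = exon minus CDS, split 5'/3' around the CDS genomic span,
# strand-aware: on "+" everything left of the CDS is 5'; on "-" it is 3'.
derive_utrs <- function(models) {
  for (i in seq_len(nrow(models))) {
    ex <- models$exons[[i]]
    cd <- models$cds[[i]]
    if (nrow(cd) == 0) {
      left <- iv_setdiff(ex, cd)
      right <- iv()
    } else {
      utr <- iv_setdiff(ex, cd)
      cds_lo <- min(cd$start)
      cds_hi <- max(cd$end)
      left <- iv_sort(dplyr::filter(utr, .data$end <= cds_lo))
      right <- iv_sort(dplyr::filter(utr, .data$start >= cds_hi))
    }
    if (models$strand[i] == "+") {
      models$utr5[[i]] <- left
      models$utr3[[i]] <- right
    } else {
      models$utr5[[i]] <- right
      models$utr3[[i]] <- left
    }
  }
  models
}

parse_gff3_attributes <- function(attr) {
  pairs <- strsplit(attr, ";", fixed = TRUE)
  lapply(pairs, function(p) {
    p <- p[nzchar(p)]
    kv <- strsplit(p, "=", fixed = TRUE)
    setNames(
      vapply(kv, function(x) paste(x[-1], collapse = "="), character(1)),
      vapply(kv, `[[`, character(1), 1)
    )
  })
}

#' Read gene models from a GFF3 file
#'
#' Consumes `gene`/`mRNA`/`exon`/`CDS` features linked by `ID`/`Parent`.
#' GFF3 1-based inclusive coordinates become 0-based half-open. UTRs are
#' re-derived as exon minus CDS regardless of any UTR features present.
#'
#' @param file path to a GFF3 file, or a scalar of GFF3 text.
#' @return gene-model tibble sorted by (seq_id, start).
#' @export
read_gff3 <- function(file) {
  if (length(file) == 1 && grepl("\n", file)) {
    lines <- strsplit(file, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- readLines(file)
  }
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) return(empty_gene_models())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9)) {
    abort(sprintf("GFF3 line %d does not have 9 columns", which(nf != 9)[1]),
      class = "genesetqc_gff3_error")
  }
  f <- as_tibble(do.call(rbind, fields), .name_repair = "minimal")
  names(f) <- c("seq_id", "source", "type", "start", "end",
                "score", "strand", "phase", "attributes")
  f$start <- as.integer(f$start) - 1L  # to 0-based half-open
  f$end <- as.integer(f$end)
  at <- parse_gff3_attributes(f$attributes)
  f$ID <- vapply(at, function(a) a["ID"] %||% NA_character_, character(1))
  f$Parent <- vapply(at, function(a) a["Parent"] %||% NA_character_, character(1))
  f$partial_attr <- vapply(at, function(a) a["partial"] %||% "", character(1))

  genes <- f[f$type == "gene", ]
  mrnas <- f[f$type == "mRNA", ]
  orphan <- !(mrnas$Parent %in% genes$ID)
  if (any(orphan)) {
    abort(sprintf("mRNA with unknown Parent: %s",
      paste(mrnas$Parent[orphan], collapse = ", ")),
      class = "genesetqc_gff3_error")
  }
  parts <- f[f$type %in% c("exon", "CDS"), ]
  known <- parts$Parent %in% mrnas$ID
  if (any(!known)) {
    abort(sprintf("%s with unknown Parent: %s", parts$type[!known][1],
      paste(unique(parts$Parent[!known]), collapse = ", ")),
      class = "genesetqc_gff3_error")
  }

  rows <- lapply(seq_len(nrow(mrnas)), function(i) {
    mid <- mrnas$ID[i]
    ex <- parts[parts$Parent == mid & parts$type == "exon", ]
    cd <- parts[parts$Parent == mid & parts$type == "CDS", ]
    partial <- strsplit(mrnas$partial_attr[i], ",", fixed = TRUE)[[1]]
    gene_model(
      seq_id = mrnas$seq_id[i],
      locus_id = mrnas$Parent[i],
      isoform_id = mid,
      strand = mrnas$strand[i],
      exons = iv(ex$start, ex$end),
      cds = iv(cd$start, cd$end),
      partial5 = "5" %in% partial,
      partial3 = "3" %in% partial
    )
  })
  arrange(bind_rows(rows), .data$seq_id, .data$start, .data$isoform_id)
}

empty_gene_models <- function() {
  tibble(
    seq_id = character(), locus_id = character(), isoform_id = character(),
    strand = character(), start = integer(), end = integer(),
    exons = list(), cds = list(), utr5 = list(), utr3 = list(),
    partial5 = logical(), partial3 = logical()
  )
}

#' Write gene models to GFF3
#'
#' Emits gene/mRNA/exon/CDS features with deterministic attribute order;
#' round-trips with [read_gff3()] on spans, exons, CDS, strand and ids.
#'
#' @param models gene-model tibble.
#' @param file output path.
#' @param source value for GFF3 column 2.
#' @return `file`, invisibly.
#' @export
write_gff3 <- function(models, file, source = "genesetqc") {
  models <- arrange(models, .data$seq_id, .data$start, .data$isoform_id)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  line <- function(seq_id, type, start, end, strand, phase, attrs) {
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t%s\t%s",
      seq_id, source, type, start + 1L, end, strand, phase, attrs)
  }
  for (locus in unique(models$locus_id)) {
    iso <- models[models$locus_id == locus, ]
    writeLines(line(iso$seq_id[1], "gene", min(iso$start), max(iso$end),
      iso$strand[1], ".", sprintf("ID=%s", locus)), con)
    for (i in seq_len(nrow(iso))) {
      partial <- c(if (iso$partial5[i]) "5", if (iso$partial3[i]) "3")
      pattr <- if (length(partial) > 0) {
        sprintf(";partial=%s", paste(partial, collapse = ","))
      } else ""
      writeLines(line(iso$seq_id[i], "mRNA", iso$start[i], iso$end[i],
        iso$strand[i], ".",
        sprintf("ID=%s;Parent=%s%s", iso$isoform_id[i], locus, pattr)), con)
      ex <- iso$exons[[i]]
      for (j in seq_len(nrow(ex))) {
        writeLines(line(iso$seq_id[i], "exon", ex$start[j], ex$end[j],
          iso$strand[i], ".", sprintf("Parent=%s", iso$isoform_id[i])), con)
      }
      cd <- iso$cds[[i]]
      if (nrow(cd) > 0) {
        # phase: bases to skip to reach the next codon start, in
        # transcription order
        tx_order <- if (iso$strand[i] == "+") seq_len(nrow(cd)) else rev(seq_len(nrow(cd)))
        lens <- (cd$end - cd$start)[tx_order]
        phase <- (3L - (cumsum(dplyr::lag(lens, default = 0L)) %% 3L)) %% 3L
        phase_genomic <- integer(nrow(cd))
        phase_genomic[tx_order] <- phase
        for (j in seq_len(nrow(cd))) {
          writeLines(line(iso$seq_id[i], "CDS", cd$start[j], cd$end[j],
            iso$strand[i], as.character(phase_genomic[j]),
            sprintf("Parent=%s", iso$isoform_id[i])), con)
        }
      }
    }
  }
  invisible(file)
}
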