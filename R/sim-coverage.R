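# Simulated per-base coverage with planted support classes. Each library
# draws a support class per gene; exon bases get Poisson counts at a rate
# placed well away from the 5 reads-per-base decision threshold
# (supported: mean in [8,15]; low coverage: mean in [1.5,2.5]), one
# CDS-bearing exon is zeroed for unsupported_exon genes, and intergenic
# background is sparse noise (rate 0.01/base). Protein-homology evidence
# (reference coverage fraction and truncated end) is planted per gene and
# combined into the expected quality tag.

#' Simulate coverage tracks with planted support classes
#'
#' @param genome sequence table (the reference genome).
#' @param models gene-model tibble on that genome.
#' @param support_mix named proportions over support classes.
#' @param n_libraries number of independent libraries.
#' @param seed integer seed.
#' @return list: `tracks` (list of coverage tibbles, one per library) and
#'   `truth_support` (per gene: realised planted class and mean per
#'   library, homology fraction, truncated end, expected quality tag).
#' @export
simulate_coverage <- function(genome, models, support_mix = default_support_mix(),
                              n_libraries = 2, seed = 1) {
  with_seed(child_seed(seed, 3), {
    n <- nrow(models)
    glens <- setNames(nchar(genome$residues), genome$id)

    class_mat <- matrix(NA_character_, n, n_libraries)
    mean_mat <- matrix(0, n, n_libraries)
    tracks <- vector("list", n_libraries)
    for (k in seq_len(n_libraries)) {
      counts <- lapply(glens, function(L) {
        noise <- integer(L)
        hit <- runif(L) < 0.01
        noise[hit] <- 1L
        noise
      })
      classes <- sample(rep(names(support_mix), mix_counts(support_mix, n)))
      for (i in seq_len(n)) {
        m <- models[i, ]
        ex <- m$exons[[1]]
        if (classes[i] == "unsupported_exon" && nrow(ex) < 2) {
          classes[i] <- "low_coverage"  # needs a second exon to zero
        }
        sid <- m$seq_id[1]
        if (classes[i] == "no_coverage") {
          counts[[sid]][(m$start[1] + 1):m$end[1]] <- 0L
          mean_mat[i, k] <- 0
        } else {
          lam <- switch(classes[i],
            supported = runif(1, 8, 15),
            low_coverage = runif(1, 1.5, 2.5),
            unsupported_exon = runif(1, 8, 15))
          for (j in seq_len(nrow(ex))) {
            idx <- (ex$start[j] + 1):ex$end[j]
            counts[[sid]][idx] <- rpois(length(idx), lam)
          }
          if (classes[i] == "unsupported_exon") {
            drop <- sample(nrow(ex), 1)
            counts[[sid]][(ex$start[drop] + 1):ex$end[drop]] <- 0L
          }
          mean_mat[i, k] <- lam
        }
        class_mat[i, k] <- classes[i]
      }
      tracks[[k]] <- tibble(seq_id = names(counts),
        counts = unname(counts))
    }

    # planted homology: most genes full length, the rest truncated
    full <- runif(n) < 0.8
    frac <- ifelse(full, runif(n, 0.92, 1.0), runif(n, 0.5, 0.8))
    m_end <- ifelse(full, NA_character_, sample(c("5", "3"), n, replace = TRUE))
    expected_tag <- vapply(seq_len(n), function(i) {
      assign_quality_tag(class_mat[i, ], frac[i], m_end[i])$tag
    }, character(1))

    ts <- tibble(
      gene_id = models$locus_id,
      isoform_id = models$isoform_id,
      ref_coverage_fraction = frac,
      missing_end = m_end,
      expected_tag = expected_tag
    )
    for (k in seq_len(n_libraries)) {
      ts[[paste0("class_lib", k)]] <- class_mat[, k]
      ts[[paste0("mean_lib", k)]] <- mean_mat[, k]
    }
    list(tracks = tracks, truth_support = ts)
  })
}

#' Write a full simulation to disk
#'
#' Writes genome and variant genome FASTA, both GFF3 gene sets, CDS and
#' protein FASTA for both genotypes, per-library coverage TSV and the
#' truth tables as TSV.
#'
#' @param dir output directory (created if needed).
#' @param config [sim_config()].
#' @return invisible list of the generated objects.
#' @export
write_simulation <- function(dir, config = sim_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- generate_truth_set(config)
  variant <- derive_comparison_set(truth, config)
  cov <- simulate_coverage(truth$genome, truth$models, config$support_mix,
    config$n_libraries, config$seed)
  write_fasta(truth$genome, file.path(dir, "genome.fa"))
  write_gff3(truth$models, file.path(dir, "truth.gff3"))
  write_fasta(truth$cds, file.path(dir, "truth_cds.fa"))
  write_fasta(truth$proteins, file.path(dir, "truth_pep.fa"))
  write_fasta(variant$genome, file.path(dir, "variant_genome.fa"))
  write_gff3(variant$models, file.path(dir, "variant.gff3"))
  write_fasta(variant$cds, file.path(dir, "variant_cds.fa"))
  write_fasta(variant$proteins, file.path(dir, "variant_pep.fa"))
  for (k in seq_along(cov$tracks)) {
    write_coverage(cov$tracks[[k]], file.path(dir,
      sprintf("coverage_lib%d.tsv", k)))
  }
  readr::write_tsv(variant$truth, file.path(dir, "truth_table.tsv"),
    progress = FALSE)
  readr::write_tsv(cov$truth_support, file.path(dir, "truth_support.tsv"),
    progress = FALSE)
  invisible(list(truth = truth, variant = variant, coverage = cov))
}
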