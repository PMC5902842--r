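# Simulation configuration. The defaults define the study conditions the
# package is tested under: a paired-genotype design in which a reference
# gene set is copied, perturbed per planted comparison category, and
# accompanied by per-base coverage tracks with planted support classes.

#' Default mixes
#'
#' @name sim_mixes
#' @keywords internal
NULL

default_category_mix <- function() {
  c(
    identical_equal_length = 0.30,
    query_contained = 0.06,
    target_contained = 0.06,
    binned_match = 0.30,
    cds_only_match = 0.05,
    encapsulated_in_utr = 0.05,
    overlaps_5utr = 0.04,
    overlaps_3utr = 0.04,
    present_no_match = 0.05,
    missing_from_genome = 0.05
  )
}

default_bin_mix <- function() {
  c(
    "0-59" = 0.04, "60-64" = 0.06, "65-69" = 0.06, "70-74" = 0.08,
    "75-79" = 0.08, "80-84" = 0.10, "85-89" = 0.12, "90-94" = 0.16,
    "95-99" = 0.30
  )
}

default_support_mix <- function() {
  c(supported = 0.55, low_coverage = 0.20, unsupported_exon = 0.15,
    no_coverage = 0.10)
}

# centre of each identity bin targeted by the mutation engine; chosen so
# that the +/- 2 point realisation tolerance stays inside the bin
BIN_TARGETS <- c(
  "0-59" = 55, "60-64" = 62, "65-69" = 67, "70-74" = 72, "75-79" = 77,
  "80-84" = 82, "85-89" = 87, "90-94" = 92, "95-99" = 97
)

#' Simulation configuration
#'
#' @param seed integer; fully determines all outputs.
#' @param n_genes number of reference genes.
#' @param genome_len total genome length in bases; NULL sizes the genome
#'   to fit the genes plus intergenic spacing.
#' @param gc genome GC fraction (default 0.36, a typical plant value).
#' @param n_seqs number of chromosomes.
#' @param category_mix named proportions over the ten comparison
#'   categories (must sum to 1).
#' @param bin_mix named proportions over the identity bins planted for
#'   `binned_match` genes.
#' @param support_mix named proportions over coverage support classes.
#' @param n_libraries number of simulated coverage libraries.
#' @return config list.
#' @export
sim_config <- function(seed = 1, n_genes = 200, genome_len = NULL,
                       gc = 0.36, n_seqs = 2,
                       category_mix = default_category_mix(),
                       bin_mix = default_bin_mix(),
                       support_mix = default_support_mix(),
                       n_libraries = 2) {
  for (mix in list(category_mix, bin_mix, support_mix)) {
    if (abs(sum(mix) - 1) > 1e-8) {
      abort("mix proportions must sum to 1", class = "genesetqc_sim_error")
    }
  }
  list(seed = as.integer(seed), n_genes = n_genes, genome_len = genome_len,
    gc = gc, n_seqs = n_seqs, category_mix = category_mix,
    bin_mix = bin_mix, support_mix = support_mix,
    n_libraries = n_libraries)
}

# deterministic integer counts from proportions: largest-remainder rounding
mix_counts <- function(mix, n) {
  raw <- mix * n
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)), collapse = "")
}

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
  c("TAA", "TAG", "TGA"))
STOP_CODONS <- c("TAA", "TAG", "TGA")

random_cds <- function(n_codons) {
  paste0("ATG",
    paste(sample(SENSE_CODONS, n_codons - 2, replace = TRUE), collapse = ""),
    sample(STOP_CODONS, 1))
}
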