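# Independent oracles and random-fixture builders shared across tests.
# Each oracle is a deliberately naive reimplementation kept separate from
# the package's own code paths.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
  "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
  collapse = "")

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n,
  replace = TRUE), collapse = "")

# full-matrix affine-gap local alignment score, O(nm) with explicit
# three-state recurrences; gap of length L costs open + ext * L
oracle_local_score <- function(q, t, mat, open, ext) {
  qc <- strsplit(q, "")[[1]]
  tc <- strsplit(t, "")[[1]]
  n <- length(qc)
  m <- length(tc)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[qc[i - 1], tc[j - 1]],
        E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# naive longest-ORF search over all six frames using Biostrings
# translation; returns the winning protein, frame and whether a stop
# terminates it
oracle_longest_orf <- function(s, min_len = 30) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  best <- NULL
  for (f in c(1, 2, 3, -1, -2, -3)) {
    src <- if (f > 0) s else rc
    off <- abs(f) - 1
    sub <- substring(src, off + 1, nchar(src))
    sub <- substring(sub, 1, 3 * (nchar(sub) %/% 3))
    if (nchar(sub) < 3) next
    prot <- as.character(Biostrings::translate(Biostrings::DNAString(sub),
      if.fuzzy.codon = "X", no.init.codon = TRUE))
    starts <- gregexpr("M[^*]*", prot)[[1]]
    if (starts[1] < 0) next
    lens <- attr(starts, "match.length")
    for (k in seq_along(starts)) {
      plen <- lens[k]
      if (plen < min_len) next
      end_pos <- starts[k] + plen - 1
      has_stop <- end_pos < nchar(prot) &&
        substring(prot, end_pos + 1, end_pos + 1) == "*"
      cand <- list(protein = substring(prot, starts[k], end_pos),
        frame = f, partial3 = !has_stop, plen = plen)
      if (is.null(best) || cand$plen > best$plen) best <- cand
    }
  }
  best
}

# cumulative-sum Nx/Lx oracle
oracle_nx <- function(lengths, frac) {
  s <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(s)
  i <- which(cum >= frac * sum(s))[1]
  list(n = s[i], l = i)
}

two_exon_model <- function(intron_len) {
  gene_model("chr1", "g1", "+",
    exons = iv_df(c(0, 100 + intron_len), c(100, 200 + intron_len)),
    cds = iv_df(c(10, 100 + intron_len), c(100, 190 + intron_len)))
}

iv_df <- function(start, end) {
  tibble::tibble(start = as.integer(start), end = as.integer(end))
}

# a tiny hand-built two-gene GFF3 text
tiny_gff3 <- function() {
  paste(
    "##gff-version 3",
    "chr1\ttest\tgene\t1\t90\t.\t+\t.\tID=g1",
    "chr1\ttest\tmRNA\t1\t90\t.\t+\t.\tID=g1.1;Parent=g1",
    "chr1\ttest\texon\t1\t90\t.\t+\t.\tParent=g1.1",
    "chr1\ttest\tCDS\t31\t60\t.\t+\t.\tParent=g1.1",
    sep = "\n"
  )
}

small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 11, n_genes = 30)
      tr <- generate_truth_set(cfg)
      va <- derive_comparison_set(tr, cfg)
      cache <<- list(cfg = cfg, truth = tr, variant = va)
    }
    cache
  }
})
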