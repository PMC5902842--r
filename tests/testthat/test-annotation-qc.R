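test_that("small-intron lint fires below 15 bases and not at 22", {
  expect_equal(annotation_lint(two_exon_model(14))$rule, "small_intron")
  expect_equal(nrow(annotation_lint(two_exon_model(22))), 0)
  expect_equal(nrow(annotation_lint(two_exon_model(15))), 0)
})

test_that("untranslated-exon lint fires above three exons", {
  make <- function(n_utr_exons) {
    ex_starts <- seq(0, by = 150, length.out = n_utr_exons + 1)
    gene_model("chr1", "g1", "+",
      exons = iv_df(ex_starts, ex_starts + 100),
      cds = iv_df(10, 90))  # only the first exon is translated
  }
  expect_equal(annotation_lint(make(4))$rule, "many_untranslated_exons")
  expect_equal(nrow(annotation_lint(make(3))), 0)
})

test_that("sequence lint needs a genome and respects partial flags", {
  genome <- seq_records("chr1", paste0("ATG", strrep("GCT", 30), "TAACCC"))
  good <- gene_model("chr1", "g1", "+", iv_df(0, 99), iv_df(0, 96))
  expect_equal(nrow(annotation_lint(good, genome)), 0)

  # shift the CDS so it neither starts with ATG nor ends with a stop
  bad <- gene_model("chr1", "g2", "+", iv_df(0, 99), iv_df(3, 93))
  flags <- annotation_lint(bad, genome)
  expect_setequal(flags$rule, c("missing_start", "missing_stop"))

  partial <- gene_model("chr1", "g3", "+", iv_df(0, 99), iv_df(3, 93),
    partial5 = TRUE, partial3 = TRUE)
  expect_equal(nrow(annotation_lint(partial, genome)), 0)

  # internal stop: TAA inside the frame
  genome2 <- seq_records("chr1", paste0("ATG", "TAA", strrep("GCT", 10),
    "TGA"))
  stopm <- gene_model("chr1", "g4", "+", iv_df(0, 39), iv_df(0, 39))
  expect_true("internal_stop" %in% annotation_lint(stopm, genome2)$rule)

  off <- gene_model("chr1", "g5", "+", iv_df(0, 38), iv_df(0, 38))
  expect_true("cds_not_multiple_of_3" %in%
    annotation_lint(off, genome2)$rule)
})

test_that("naming is stable, padded and keeps location as a descriptor", {
  m <- dplyr::bind_rows(
    gene_model("chr1", "locA", "+", iv_df(0, 90), iv_df(0, 90)),
    gene_model("chr1", "locB", "+", iv_df(200, 290), iv_df(200, 290),
      isoform_id = "locB.i1"),
    gene_model("chr1", "locB", "+", iv_df(200, 290), iv_df(200, 260),
      isoform_id = "locB.i2")
  )
  nm <- name_genes(m)
  expect_equal(nm$locus_name[1], "Acc00001")
  expect_equal(nm$isoform_name[1], "Acc00001.1")
  expect_equal(nm$isoform_name[2:3], c("Acc00002.1", "Acc00002.2"))
  expect_equal(nm$descriptor[1], "chr1:1-90")

  # re-running reproduces identical names; appending continues the counter
  expect_equal(name_genes(m), nm)
  more <- dplyr::bind_rows(m,
    gene_model("chr1", "locC", "+", iv_df(400, 490), iv_df(400, 490)))
  nm2 <- name_genes(more)
  expect_equal(nm2$locus_name[1:3], nm$locus_name)
  expect_equal(nm2$locus_name[4], "Acc00003")

  # relocation changes only the descriptor
  moved <- m
  moved$seq_id <- "chr9"
  nm3 <- name_genes(moved)
  expect_equal(nm3$locus_name, nm$locus_name)
  expect_true(all(startsWith(nm3$descriptor, "chr9:")))

  expect_error(name_genes(m, width = 5, start_index = 99999),
    class = "genesetqc_qc_error")
})

test_that("tandem duplicates cluster by single linkage on one sequence", {
  withr::with_seed(41, p <- random_protein(100))
  p2 <- p
  substr(p2, 5, 5) <- "W"  # 99% identical
  other <- withr::with_seed(42, random_protein(100))
  mk <- function(locus, seq_id, start) {
    gene_model(seq_id, locus, "+", iv_df(start, start + 300),
      iv_df(start, start + 300))
  }
  models <- dplyr::bind_rows(
    mk("gA", "chr1", 0), mk("gB", "chr1", 400), mk("gC", "chr1", 800),
    mk("gD", "chr1", 1200), mk("gE", "chr2", 0))
  proteins <- seq_records(
    c("gA.1", "gB.1", "gC.1", "gD.1", "gE.1"),
    c(p, p2, p, other, p))
  sites <- find_tandem_duplicates(models, proteins)
  # A~B~C chain on chr1 (single linkage); D unrelated; E on another
  # sequence
  expect_equal(nrow(sites), 1)
  expect_equal(sites$n_members, 3)
  expect_equal(sites$members[[1]], c("gA", "gB", "gC"))

  # brute-force transitive-closure oracle over qualifying adjacent pairs
  adj <- list(c(1, 2), c(2, 3), c(1, 3))  # rank gaps <= 2 on chr1
  prots <- c(p, p2, p)
  qualifies <- vapply(adj, function(ab) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(prots[ab[1]]), Biostrings::AAString(prots[ab[2]]),
      type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1)
    Biostrings::nmatch(al) / 100 >= 0.9
  }, logical(1))
  expect_true(all(qualifies))

  # identical genes on different sequences never cluster
  two <- dplyr::bind_rows(mk("gX", "chr1", 0), mk("gY", "chr2", 0))
  pp <- seq_records(c("gX.1", "gY.1"), c(p, p))
  expect_equal(nrow(find_tandem_duplicates(two, pp)), 0)

  # sites are disjoint
  expect_false(any(duplicated(unlist(sites$members))))
})
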