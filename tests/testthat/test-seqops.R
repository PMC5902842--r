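test_that("translation follows the standard code and flags anomalies", {
  expect_equal(as.character(translate_cds("ATGAAATGA")), "MK")
  expect_equal(as.character(translate_cds("ATGTGA")), "M")
  expect_error(translate_cds("ATGAA"), class = "genesetqc_translate_error")
  expect_warning(p <- translate_cds("ATGAAAT", partial = TRUE), "remainder")
  expect_equal(as.character(p), "MK")
  expect_warning(translate_cds("ATGTAAAAATGA"), "internal stop")
})

test_that("translation agrees with the codon-table oracle on random CDS", {
  withr::with_seed(5, {
    for (i in 1:100) {
      s <- random_dna_str(3 * sample(2:60, 1))
      mine <- as.character(suppressWarnings(
        translate_cds(s, trim_final_stop = FALSE)))
      ref <- as.character(Biostrings::translate(Biostrings::DNAString(s),
        if.fuzzy.codon = "X", no.init.codon = TRUE))
      expect_equal(mine, ref)
    }
  })
})

test_that("six-frame translation covers both strands symmetrically", {
  fr <- six_frame_translate("ATGAAA")
  expect_equal(fr$protein[fr$frame == 1], "MK")
  withr::with_seed(6, s <- random_dna_str(60))
  fr <- six_frame_translate(s)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(fr$protein[fr$frame == -1],
    six_frame_translate(rc)$protein[1])
  # brute-force per-frame check
  for (f in 1:3) {
    sub <- substring(s, f, nchar(s))
    sub <- substring(sub, 1, 3 * (nchar(sub) %/% 3))
    expect_equal(fr$protein[fr$frame == f],
      as.character(Biostrings::translate(Biostrings::DNAString(sub),
        no.init.codon = TRUE)))
  }
})

test_that("longest ORF matches examples and the six-frame oracle", {
  r <- longest_orf("ATGAAATGA", min_protein_len = 1)
  expect_true(r$found)
  expect_equal(r$protein, "MK")
  expect_equal(r$frame, 1L)
  expect_equal(r$nt_end - r$nt_start, 9L)  # includes the stop codon

  none <- longest_orf("CCCCCC", min_protein_len = 1)
  expect_false(none$found)

  withr::with_seed(8, {
    for (i in 1:60) {
      # plant a real ORF somewhere to make hits common
      core <- paste0("ATG", paste(sample(genesetqc:::SENSE_CODONS,
        sample(8:40, 1), replace = TRUE), collapse = ""), "TAA")
      s <- paste0(random_dna_str(sample(0:30, 1)), core,
        random_dna_str(sample(0:30, 1)))
      if (i %% 2 == 0) s <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(s)))
      mine <- longest_orf(s, min_protein_len = 5)
      ref <- oracle_longest_orf(s, min_len = 5)
      expect_equal(mine$protein, ref$protein)
      expect_equal(nchar(mine$protein) * 3 <= mine$nt_end - mine$nt_start,
        TRUE)
      expect_false(grepl("*", mine$protein, fixed = TRUE))
    }
  })
})

test_that("dedup removes near-identical sequences greedily", {
  a <- strrep("ACGT", 25)
  b <- a
  substr(b, 10, 10) <- "T"   # 99% identical
  c99 <- b
  d <- a
  for (p in c(5, 25, 55)) substr(d, p, p) <- "T"  # 97% identical
  recs <- seq_records(c("a", "b", "d"), c(a, c99, d))
  res <- dedup_by_identity(recs, threshold = 0.98)
  expect_equal(sort(res$retained$id), c("a", "d"))
  expect_equal(res$clusters$representative[res$clusters$id == "b"], "a")

  # identical pair collapses
  two <- seq_records(c("x", "y"), c(a, a))
  expect_equal(nrow(dedup_by_identity(two)$retained), 1)

  # idempotence
  again <- dedup_by_identity(res$retained, threshold = 0.98)
  expect_equal(again$retained$id, res$retained$id)
})

test_that("assembly statistics match the cumulative-sum oracle", {
  s <- assembly_stats(c(100))
  expect_equal(s$n50, 100)
  expect_equal(s$l50, 1)

  s <- assembly_stats(c(5, 4, 3, 2, 1))
  expect_equal(s$n50, 4)  # cumsum 5,9 reaches 7.5 at rank 2
  expect_equal(s$l50, 2)

  s <- assembly_stats(c(10, 10, 10))
  expect_equal(c(s$n50, s$l50, s$n90, s$l90), c(10, 2, 10, 3))

  expect_error(assembly_stats(integer(0)), class = "genesetqc_stats_error")

  withr::with_seed(3, {
    for (i in 1:50) {
      lens <- sample(1:5000, sample(1:40, 1), replace = TRUE)
      s <- assembly_stats(lens)
      o50 <- oracle_nx(lens, 0.5)
      o90 <- oracle_nx(lens, 0.9)
      expect_equal(c(s$n50, s$l50, s$n90, s$l90),
        c(o50$n, o50$l, o90$n, o90$l))
      expect_true(s$n50 %in% lens)
      expect_true(s$n50 >= s$n90 && s$l50 <= s$l90)
    }
  })
})

test_that("percent N is computed from sequences", {
  s <- assembly_stats(seq_records(c("a", "b"), c("ACGTNN", "NNNN")))
  expect_equal(s$percent_N, 60)
})

test_that("scaffold concatenation round-trips through the coordinate map", {
  sc <- seq_records(c("s1", "s2"), c("AC", "GT"))
  res <- concatenate_scaffolds(sc, spacer_n = 2)
  expect_equal(res$record$residues, "ACNNGT")
  expect_equal(res$map$start, c(0L, 4L))
  expect_equal(res$map$end, c(2L, 6L))

  one <- concatenate_scaffolds(sc[1, ], spacer_n = 10)
  expect_equal(one$record$residues, "AC")

  withr::with_seed(4, {
    many <- seq_records(sprintf("s%d", 1:10),
      vapply(1:10, function(i) random_dna_str(sample(5:80, 1)), character(1)))
  })
  res <- concatenate_scaffolds(many, spacer_n = 100)
  expect_equal(split_composite(res$record, res$map)$residues, many$residues)
})
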