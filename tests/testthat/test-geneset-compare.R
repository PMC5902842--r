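minus_model <- function() {
  gene_model("chr1", "gT", "-",
    exons = iv_df(100, 400), cds = iv_df(200, 300))
}

test_that("UTR relations are strand-aware with 5' precedence", {
  m <- minus_model()
  # minus strand: genomic-left exon-minus-CDS region is the 3' UTR
  expect_equal(m$utr3[[1]], iv_df(100, 200))
  expect_equal(m$utr5[[1]], iv_df(300, 400))

  span <- function(s, e) list(seq_id = "chr1", start = s, end = e)
  expect_equal(utr_relation(span(120, 180), m), "encapsulated_in_utr")
  expect_equal(utr_relation(span(50, 150), m), "overlaps_3utr")
  expect_equal(utr_relation(span(350, 450), m), "overlaps_5utr")
  # hits both UTRs and the CDS: 5' wins
  expect_equal(utr_relation(span(150, 350), m), "overlaps_5utr")
  expect_equal(utr_relation(list(seq_id = "chr2", start = 120, end = 180), m),
    "none")
  # plus strand: query inside 3' UTR only
  p <- gene_model("chr1", "gP", "+",
    exons = iv_df(0, 300), cds = iv_df(50, 150))
  expect_equal(utr_relation(span(200, 250), p), "encapsulated_in_utr")
  expect_equal(utr_relation(span(250, 350), p), "overlaps_3utr")
})

test_that("identity bins partition [0,100] with an exact 100 bin", {
  bt <- bin_identities(c(100))
  expect_equal(bt$count[bt$bin == "100"], 1L)
  bt <- bin_identities(c(99.4))
  expect_equal(bt$count[bt$bin == "95-99"], 1L)
  expect_equal(bt$count[bt$bin == "100"], 0L)
  bt <- bin_identities(c(0, 59.9, 60, 95, NA, 89.999))
  expect_equal(sum(bt$count), 6L)
  expect_equal(bt$count[bt$bin == "0-59"], 2L)
  expect_equal(bt$count[bt$bin == "no_match"], 1L)
  expect_error(bin_identities(c(101)), class = "genesetqc_compare_error")
})

test_that("headline fractions reproduce the published worked example", {
  f <- system.file("extdata", "hort16a_identity_bins.tsv",
    package = "genesetqc")
  counts <- readr::read_tsv(f, show_col_types = FALSE)
  # each column is a complete 550-protein test-set tally
  expect_equal(sum(counts$red5), 550)
  expect_equal(sum(counts$hongyang_original), 550)
  expect_equal(sum(counts$hongyang_revised), 550)
  tab <- function(col) tibble::tibble(bin = counts$bin, count = counts[[col]])
  expect_equal(fraction_at_threshold(tab("red5"), 90), 90.9)
  expect_equal(fraction_at_threshold(tab("hongyang_original"), 90), 48.9)
  expect_equal(fraction_at_threshold(tab("hongyang_revised"), 90), 63.5)
  all_no <- tibble::tibble(bin = "no_match", count = 10L)
  expect_equal(fraction_at_threshold(all_no, 90), 0)
})

test_that("the report formatter rounds half-up to one decimal", {
  expect_equal(percent_of(3114, 33123), 9.4)
  expect_equal(round_half_up(63.45, 1), 63.5)
  expect_equal(round_half_up(63.44, 1), 63.4)
})

test_that("classify_model follows the cascade on hand-built sets", {
  withr::with_seed(21, {
    p1 <- random_protein(80)
    p2 <- random_protein(60)
  })
  targets <- gene_set(seq_records(c("t1", "t2"), c(p1, p2)))
  # identical
  r <- classify_model(seq_records("q", p1), NULL, targets)
  expect_equal(r$category, "identical_equal_length")
  expect_equal(r$bin, "100")
  expect_equal(r$length_relation, "equal")
  # query strictly inside a target
  r <- classify_model(seq_records("q", substring(p1, 10, 60)), NULL, targets)
  expect_equal(r$category, "query_contained")
  expect_equal(r$percent_identity, 100)
  # diverged but alignable
  mut <- strsplit(p1, "")[[1]]
  withr::with_seed(22, {
    at <- sample(80, 16)
    mut[at] <- sample(AA20, 16, replace = TRUE)
  })
  r <- classify_model(seq_records("q", paste(mut, collapse = "")), NULL,
    targets)
  expect_equal(r$category, "binned_match")
  expect_equal(r$best_target_id, "t1")
})

test_that("self-comparison is a fixed point", {
  tr <- small_sim()$truth
  x <- gene_set(tr$proteins, tr$cds, tr$models, tr$genome)
  cmp <- compare_genesets(x, x)
  expect_equal(
    sum(tidy(cmp)$category == "identical_equal_length"), cmp$n_queries)
  expect_equal(nrow(cmp$rbm), cmp$n_queries)
  expect_equal(fraction_at_threshold(cmp$bin_table), 100)
})

test_that("planted categories and bins are recovered on the small pair", {
  s <- small_sim()
  cmp <- compare_genesets(
    gene_set(s$truth$proteins, s$truth$cds, s$truth$models, s$truth$genome),
    gene_set(s$variant$proteins, s$variant$cds, s$variant$models,
      s$variant$genome))
  j <- dplyr::inner_join(s$variant$truth, tidy(cmp),
    by = c(isoform_id = "query_id"))
  expect_equal(nrow(j), nrow(s$variant$truth))
  expect_equal(j$category.y, j$category.x)
  b <- j[j$category.x == "binned_match", ]
  bin_idx <- function(x) match(x, genesetqc:::IDENTITY_BIN_LEVELS)
  expect_true(all(abs(bin_idx(b$bin) - bin_idx(b$planted_bin)) <= 1))
  # counts conserve queries
  expect_equal(sum(cmp$category_counts$count), cmp$n_queries)
  expect_equal(sum(cmp$bin_table$count), cmp$n_queries)
})

test_that("removing the genome collapses placement categories", {
  s <- small_sim()
  cmp <- compare_genesets(
    gene_set(s$truth$proteins, s$truth$cds, s$truth$models, s$truth$genome),
    gene_set(s$variant$proteins, s$variant$cds, s$variant$models))
  j <- dplyr::inner_join(s$variant$truth, tidy(cmp),
    by = c(isoform_id = "query_id"))
  placement_cats <- c("encapsulated_in_utr", "overlaps_5utr",
    "overlaps_3utr", "missing_from_genome", "present_no_match")
  affected <- j[j$category.x %in% placement_cats, ]
  expect_true(all(affected$category.y == "present_no_match"))
  unaffected <- j[!j$category.x %in% placement_cats, ]
  expect_equal(unaffected$category.y, unaffected$category.x)
})

test_that("lowering the protein-identity floor never loses binned matches", {
  s <- small_sim()
  q <- gene_set(s$truth$proteins, s$truth$cds)
  t <- gene_set(s$variant$proteins, s$variant$cds)
  n_binned <- function(min_id) {
    cmp <- compare_genesets(q, t,
      config = cascade_config(min_protein_identity = min_id))
    sum(tidy(cmp)$category == "binned_match")
  }
  counts <- vapply(c(80, 50, 30, 0), n_binned, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("empty query sets are rejected", {
  expect_error(
    compare_genesets(gene_set(seq_records(character(0), character(0))),
      gene_set(seq_records("t", "MKL"))),
    class = "genesetqc_compare_error")
})
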