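test_that("generation is deterministic and structurally clean", {
  cfg <- sim_config(seed = 51, n_genes = 12)
  a <- generate_truth_set(cfg)
  b <- generate_truth_set(cfg)
  expect_identical(a, b)

  # models pass lint with zero flags, including sequence rules
  expect_equal(nrow(annotation_lint(a$models, a$genome)), 0)
  # introns are never shorter than 22 bases
  introns <- dplyr::bind_rows(lapply(seq_len(nrow(a$models)), function(i) {
    genesetqc:::iv_gaps(a$models$exons[[i]], a$models$start[i],
      a$models$end[i])
  }))
  if (nrow(introns) > 0) expect_true(all(introns$end - introns$start >= 22))
  # stored CDS/protein agree with the genome
  for (i in seq_len(nrow(a$models))) {
    s <- model_cds_sequence(a$models[i, ], a$genome)
    expect_equal(s, a$cds$residues[match(a$models$isoform_id[i], a$cds$id)])
  }
})

test_that("an empty gene set still yields a valid genome", {
  cfg <- sim_config(seed = 52, n_genes = 0)
  a <- generate_truth_set(cfg)
  expect_equal(nrow(a$models), 0)
  expect_gt(sum(nchar(a$genome$residues)), 0)
})

test_that("a too-small genome length is rejected with the minimum", {
  cfg <- sim_config(seed = 53, n_genes = 10, genome_len = 1000)
  expect_error(generate_truth_set(cfg), "at least",
    class = "genesetqc_sim_error")
})

test_that("mutation reaches target identities within two points", {
  withr::with_seed(54, cds <- paste0("ATG",
    paste(sample(genesetqc:::SENSE_CODONS, 98, replace = TRUE),
      collapse = ""), "TAA"))
  expect_equal(mutate_to_target_identity(cds, 100, 1)$cds, cds)
  for (target in c(90, 75, 60)) {
    res <- mutate_to_target_identity(cds, target, 1)
    # re-measure with the alignment module
    p0 <- as.character(translate_cds(cds))
    p1 <- as.character(translate_cds(res$cds))
    al <- local_align(seq_records("m", p1), seq_records("o", p0),
      protein_scoring())
    measured <- 100 * al$matches / nchar(p1)
    expect_lte(abs(measured - target), 2)
    expect_equal(measured, res$realized)
    # no stops introduced
    expect_false(grepl("*", p1, fixed = TRUE))
  }
})

test_that("short genes either reach the target or fail loudly", {
  withr::with_seed(55, cds <- paste0("ATG",
    paste(sample(genesetqc:::SENSE_CODONS, 58, replace = TRUE),
      collapse = ""), "TGA"))
  res <- tryCatch(mutate_to_target_identity(cds, 50, 2),
    genesetqc_sim_error = function(e) NULL)
  if (!is.null(res)) {
    expect_lte(abs(res$realized - 50), 2)
  } else {
    succeed()
  }
})

test_that("an all-identical mix derives a carbon-copy gene set", {
  cfg <- sim_config(seed = 56, n_genes = 8,
    category_mix = c(identical_equal_length = 1))
  tr <- generate_truth_set(cfg)
  va <- derive_comparison_set(tr, cfg)
  expect_equal(nrow(va$models), 8)
  expect_equal(sort(va$proteins$residues), sort(tr$proteins$residues))
  cmp <- compare_genesets(gene_set(tr$proteins, tr$cds),
    gene_set(va$proteins, va$cds))
  expect_true(all(tidy(cmp)$category == "identical_equal_length"))
})

test_that("derivation realises containment in both directions", {
  s <- small_sim()
  tt <- s$variant$truth
  for (i in which(tt$category == "target_contained")) {
    vp <- s$variant$proteins$residues[
      match(tt$variant_id[i], s$variant$proteins$id)]
    qp <- s$truth$proteins$residues[match(tt$isoform_id[i], s$truth$proteins$id)]
    expect_equal(exact_relation(qp, vp), "target_contained_in_query")
  }
  for (i in which(tt$category == "query_contained")) {
    vp <- s$variant$proteins$residues[
      match(tt$variant_id[i], s$variant$proteins$id)]
    qp <- s$truth$proteins$residues[match(tt$isoform_id[i], s$truth$proteins$id)]
    expect_equal(exact_relation(qp, vp), "query_contained_in_target")
  }
  # genes planted missing are masked out of the variant genome
  for (i in which(tt$category == "missing_from_genome")) {
    m <- s$truth$models[s$truth$models$isoform_id == tt$isoform_id[i], ]
    region <- substring(
      s$variant$genome$residues[match(m$seq_id, s$variant$genome$id)],
      m$start + 1, m$end)
    expect_equal(unique(strsplit(region, "")[[1]]), "N")
  }
})

test_that("simulated coverage recovers planted support classes and tags", {
  cfg <- sim_config(seed = 57, n_genes = 30)
  tr <- generate_truth_set(cfg)
  cov <- simulate_coverage(tr$genome, tr$models, n_libraries = 2,
    seed = cfg$seed)
  expect_identical(cov,
    simulate_coverage(tr$genome, tr$models, n_libraries = 2,
      seed = cfg$seed))
  tags <- quality_tags(tr$models, cov$tracks,
    homology = tibble::tibble(
      model_id = cov$truth_support$isoform_id,
      ref_coverage_fraction = cov$truth_support$ref_coverage_fraction,
      missing_end = cov$truth_support$missing_end))
  j <- dplyr::inner_join(cov$truth_support, tags,
    by = c(isoform_id = "model_id"))
  expect_equal(j$class_lib1.y, j$class_lib1.x)
  expect_equal(j$class_lib2.y, j$class_lib2.x)
  expect_equal(j$tag, j$expected_tag)
})

test_that("write_simulation emits a parseable file bundle", {
  dir <- withr::local_tempdir()
  write_simulation(dir, sim_config(seed = 58, n_genes = 6))
  expect_true(all(file.exists(file.path(dir, c(
    "genome.fa", "truth.gff3", "truth_cds.fa", "truth_pep.fa",
    "variant_genome.fa", "variant.gff3", "coverage_lib1.tsv",
    "truth_table.tsv")))))
  models <- read_gff3(file.path(dir, "truth.gff3"))
  expect_equal(nrow(models), 6)
  cov <- read_coverage(file.path(dir, "coverage_lib1.tsv"))
  genome <- read_fasta(file.path(dir, "genome.fa"))
  expect_equal(vapply(cov$counts, length, integer(1)),
    nchar(genome$residues)[match(cov$seq_id, genome$id)])
})
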