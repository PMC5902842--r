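test_that("exact relations use substring semantics with identity precedence", {
  expect_equal(exact_relation("MKV", "MKV"), "identical_equal_length")
  expect_equal(exact_relation("KVL", "MKVLA"), "query_contained_in_target")
  expect_equal(exact_relation("MKVLA", "KVL"), "target_contained_in_query")
  expect_equal(exact_relation("MKW", "AWA"), "none")
  expect_error(exact_relation("MKW", "ACGT"), class = "genesetqc_align_error")
})

test_that("local alignment counts matches deterministically", {
  withr::with_seed(2, p <- random_protein(50))
  al <- local_align(seq_records("a", p), seq_records("b", p))
  expect_equal(al$matches, 50L)
  expect_equal(c(al$query_start, al$query_end), c(0L, 50L))
  expect_equal(c(al$target_start, al$target_end), c(0L, 50L))

  al <- local_align(seq_records("a", "MKVL"), seq_records("b", "MAVL"))
  expect_equal(al$matches, 3L)
  expect_equal(percent_identity(al), 75)
})

test_that("aligner score equals the dynamic-programming oracle", {
  sc <- protein_scoring()
  dn <- dna_scoring()
  withr::with_seed(10, {
    for (i in 1:80) {
      if (i %% 2 == 0) {
        q <- random_protein(sample(5:60, 1))
        t <- random_protein(sample(5:60, 1))
        s <- sc
      } else {
        q <- random_dna_str(sample(5:60, 1))
        t <- random_dna_str(sample(5:60, 1))
        s <- dn
      }
      mine <- local_align(seq_records("q", q), seq_records("t", t), s)
      ref <- oracle_local_score(q, t, s$matrix, s$gap_open, s$gap_ext)
      expect_equal(mine$score, ref)
      # score symmetry under symmetric scoring (co-optimal tracebacks of
      # unrelated pairs may differ in matched-residue counts, the optimal
      # score never does)
      swapped <- local_align(seq_records("t", t), seq_records("q", q), s)
      expect_equal(swapped$score, mine$score)
    }
  })
})

test_that("aligner agrees with an independent library implementation", {
  withr::with_seed(12, {
    for (i in 1:20) {
      q <- random_protein(sample(20:80, 1))
      t <- random_protein(sample(20:80, 1))
      mine <- local_align(seq_records("q", q), seq_records("t", t),
        protein_scoring())
      ref <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(q), Biostrings::AAString(t),
        type = "local", substitutionMatrix = "BLOSUM62",
        gapOpening = 11, gapExtension = 1)
      expect_equal(mine$score, Biostrings::score(ref))
    }
  })
})

test_that("percent identity respects the denominator convention", {
  m <- tibble::tibble(matches = 90L, query_len = 100L, target_len = 300L)
  expect_equal(percent_identity(m), 90)
  expect_equal(percent_identity(m, "shorter_len"), 90)
  m2 <- tibble::tibble(matches = 90L, query_len = 300L, target_len = 100L)
  expect_equal(percent_identity(m2, "shorter_len"), 90)
  expect_equal(percent_identity(m2), 30)
})

test_that("best-match selection maximises matches with deterministic ties", {
  withr::with_seed(13, {
    t1 <- random_protein(60)
    t2 <- random_protein(60)
  })
  queries <- seq_records("q1", t1)
  targets <- seq_records(c("tB", "tA", "tC"), c(t2, t1, t1))
  bm <- best_match_table(queries, targets)
  expect_equal(bm$target_id, "tA")  # tie between tA and tC: lexicographic
  expect_equal(bm$percent_identity, 100)
})

test_that("planted best-match pairs are recovered among decoys", {
  withr::with_seed(14, {
    n <- 30
    planted <- vapply(1:n, function(i) random_protein(sample(60:120, 1)),
      character(1))
    decoys <- vapply(1:10, function(i) random_protein(80), character(1))
    # target = planted protein with 5 substitutions
    mutated <- vapply(planted, function(p) {
      ch <- strsplit(p, "")[[1]]
      at <- sample(length(ch), 5)
      ch[at] <- sample(AA20, 5, replace = TRUE)
      paste(ch, collapse = "")
    }, character(1))
  })
  queries <- seq_records(sprintf("q%02d", 1:n), planted)
  targets <- seq_records(c(sprintf("t%02d", 1:n), sprintf("d%02d", 1:10)),
    c(mutated, decoys))
  bm <- best_match_table(queries, targets)
  expect_equal(nrow(bm), n)
  expect_equal(bm$target_id, sprintf("t%02d", 1:n))
})

test_that("reciprocal best matches require mutual agreement", {
  q2t <- tibble::tibble(query_id = c("A", "B"), target_id = c("X", "Y"))
  t2q <- tibble::tibble(query_id = c("X", "Y"), target_id = c("A", "A"))
  rbm <- reciprocal_best_matches(q2t, t2q)
  expect_equal(rbm$query_id, "A")
  expect_equal(rbm$target_id, "X")
})

test_that("PSL input is used verbatim instead of re-aligning", {
  psl <- read_psl(paste(
    paste(90, 5, 0, 0, 0, 0, 0, 0, "+", "q1", 100, 0, 95, "tZ", 200,
      10, 105, 1, "95,", "0,", "10,", sep = "\t"),
    paste(80, 5, 0, 0, 0, 0, 0, 0, "+", "q1", 100, 0, 85, "tY", 200,
      10, 95, 1, "85,", "0,", "10,", sep = "\t"),
    sep = "\n"))
  bm <- best_match_table(seq_records("q1", strrep("A", 100)),
    seq_records("tZ", strrep("C", 200)),
    alignments = psl_as_matches(psl))
  expect_equal(bm$target_id, "tZ")
  expect_equal(bm$matches, 90L)
  expect_equal(bm$percent_identity, 90)
})
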