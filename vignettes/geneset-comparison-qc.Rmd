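---
title: "Comparing gene sets across genotypes and scoring annotation support"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing gene sets across genotypes and scoring annotation support}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genesetqc)
library(dplyr)
```

## The problem

When two genotypes of the same species are sequenced and annotated
independently — here, two kiwifruit (*Actinidia chinensis*) cultivars — the
two predicted gene sets disagree far more than the underlying genomes do.
Some disagreements are genuine varietal polymorphism; most are artefacts of
annotation: truncated or over-extended models, models called only in one
set, coding regions that one annotation placed inside the untranslated
region (UTR) of another's gene, and models resting on regions absent from
the other assembly altogether. Quantifying these disagreements, and scoring
each gene model's evidential support, is the job of this package.

`genesetqc` provides:

* a **comparison cascade** that classifies every query gene model against a
  target gene set and genome;
* **reciprocal best-match** (RBM) detection between two protein sets;
* per-base **RNA-seq coverage support** classification and **quality
  tagging** (Q2/Q1/Q0 with F/P completeness and 5/3 truncation suffixes);
* structural **annotation lint**, stable **locus naming**, and
  **tandem-duplicate** detection;
* a seeded **synthetic-data generator** that plants known comparison
  categories, identity bins and support classes, so the whole pipeline can
  be tested against ground truth.

## The comparison cascade

Each query model carries a predicted protein and a spliced coding sequence
(CDS). The cascade asks, in order:

1. **Exact protein relation.** Is the query protein identical in sequence
   and length to a target protein (`identical_equal_length`)? Is it a
   strict substring of a longer target (`query_contained`), or does it
   strictly contain a target (`target_contained`)? Containment is exact
   substring matching, not gapped alignment: the categories deliberately
   separate "same protein, different length" from fuzzy similarity.
2. **Best protein alignment.** Otherwise the query is aligned against all
   seeded targets and the best match (most matched residues) is binned by
   percent identity (`binned_match`). Identity is matched residues divided
   by the full query length — the test-set convention — and binned into
   0–59, 60–64, …, 95–99, with 100 reserved for exact 100%.
3. **Best CDS alignment.** A query whose protein matches nothing (e.g.
   after a frameshift) may still match at the DNA level
   (`cds_only_match`).
4. **Genome placement.** A query with no sequence-level match is searched
   against the target genome. If it places, its relation to the target
   models is computed: a placement inside a locus that touches no CDS is
   `encapsulated_in_utr`; one that intersects a strand-aware 5′/3′ UTR and
   escapes the locus (or reaches into the CDS) is `overlaps_5utr` /
   `overlaps_3utr` (5′ wins when both are hit); otherwise the query is
   `present_no_match`.
5. **Missing.** A query that fails placement is `missing_from_genome`.

### What counts as "a match"

External aligners report nothing for sequence pairs below their seeding
threshold, and the published comparison treats those silences as "no
match". We make that behaviour explicit and reproducible:

* two sequences are *alignable* only if they share an exact k-mer seed
  (k = 5 for protein, 11 for DNA), echoing a BLAT-style seed requirement;
* a seeded protein alignment counts as a protein match in the cascade only
  at `min_protein_identity` ≥ 30% (query-length denominator); a CDS
  alignment counts at `min_cds_identity` ≥ 50%;
* `best_match_table()` itself applies no identity floor, so reported best
  matches are binned from 0 upward, exactly as the published bin tables
  are.

The 30/50 floors are deliberate interpretations (the source analysis never
states its implicit thresholds); both are configurable through
`cascade_config()`. They sit well below the lowest planted identity bin
(centred at 55%) and well above the identity of chance local alignments at
these sequence lengths, so the classification is insensitive to their
exact values over a wide range.

### Genome placement

Placement tiles the query CDS into exact 15-mers (step 5), finds them in
the genome in one `matchPDict` pass over both orientations, takes the
densest hit cluster, and aligns the query against the surrounding window
with the exact local aligner. A query is *placed* when the alignment
reaches ≥ 90% identity over ≥ 50% of the query (both configurable). The
affine gap model (DNA: match +1, mismatch −1, gap open 2, extend 1) makes
crossing a short intron cheaper than abandoning the downstream exon, so
spliced placements of multi-exon coding sequences are found without a
dedicated spliced aligner — which is out of scope by design. Placement
coordinates always come from annotation or alignment input where
available; the package never re-infers gene structure by spliced
alignment.

### The aligner

The pairwise aligner is an affine-gap Smith–Waterman (Gotoh) implemented
in C++ with full traceback, because the analysis needs *matched residue
counts*, not only scores. Scoring defaults: BLOSUM62 with gap open 11 /
extend 1 for protein; +1/−1 with gap open 2 / extend 1 for DNA (a gap of
length L costs open + ext·L). Determinism: the traceback starts at the
highest-scoring cell (ties: lowest target index, then lowest query index)
and prefers diagonal moves over target gaps over query gaps. The test
suite pins the implementation to an independently coded full
dynamic-programming oracle and to `Biostrings::pairwiseAlignment` on
hundreds of random pairs.

One subtlety: the optimal *score* is symmetric in the two sequences, but
for essentially unrelated pairs several co-optimal alignments exist and a
deterministic traceback may count different numbers of matched residues in
the two directions. The comparison therefore treats a pair's alignment as
one object: both reciprocal-best directions reuse the same matched counts.

## Coverage support and quality tags

Per-base coverage arrives as `bedtools genomecov -d` tables (one row per
base, zeros included — the one dialect read bit-exactly). For each model
the coverage is sliced per exon and per CDS segment in transcription
order; a 0/1 bitmap and the mean reads-per-base are computed **over CDS
bases only**. Classification cascade:

* `no_coverage` — every CDS base is zero;
* `unsupported_exon` — some CDS-bearing exon has zero coverage over its
  CDS bases (UTR-only exons are ignored: an unexpressed UTR exon says
  nothing about the coding model);
* `low_coverage` — mean < 5 reads per base;
* `supported` — mean ≥ 5 (equality goes to supported, making "less than
  5" and "greater than 5" a partition).

Quality tags combine per-library classes with protein homology: level 2 if
supported in any library (evidence is assessed library by library, and one
clean library suffices), level 1 if there is coverage but never support,
level 0 if there is no coverage anywhere but homology exists. Homology
covering ≥ 90% of the reference protein renders F (full length), else P
with the truncated end appended — "2F", "1P3", "2P5". The 0.9 fraction is
a stated default (no published value exists) and is configurable.

## Lint, naming, tandem duplicates

* Lint flags introns shorter than 15 bases (the shortest credible plant
  introns are in the low twenties), more than 3 fully untranslated exons,
  and — when a genome is supplied — missing start/stop codons, internal
  stops and out-of-frame CDS lengths, with partial-model exemptions.
* Locus names are `Acc` + a zero-padded counter (width 5), isoforms `.1`,
  `.2`, … in input order. Chromosome location is a *descriptor*, never
  part of the name: relocating a locus (or re-anchoring an assembly) must
  not rename genes.
* Tandem-duplicate sites are maximal single-linkage clusters of loci on
  one sequence, at most one intervening gene apart, with protein identity
  (matched residues over the shorter protein) ≥ 90%. The definition is an
  interpretation — the source analysis publishes only counts — and both
  knobs are arguments.

## Other conventions

* **Coordinates** are 0-based half-open internally; GFF3 I/O converts at
  the boundary, so a 1-based inclusive feature (s, e) becomes [s−1, e).
* **UTRs are always re-derived** as exon minus CDS, strand-aware, never
  trusted from UTR features: annotated UTRs are the least reliable part of
  most gene sets.
* **N50/L50**: sequences sorted descending (ties in input order), Nx is
  the length at which the cumulative sum first reaches x% of the total
  (≥, not >), Lx its 1-based rank.
* **Deduplication** (`dedup_by_identity()`) clusters greedily longest
  first at > 0.98 identity, identity being matched bases over the shorter
  sequence from an end-gap-free global alignment — the closest standard
  equivalent of cd-hit-est's redundancy notion for a planted-truth test.
* **Longest ORF** requires an ATG start and ≥ 30 aa by default; ties break
  by frame order (+1, +2, +3, −1, −2, −3), then leftmost start. The
  reference-database cull used to reduce a published ORF set to
  full-length proteins depends on an external database and is exposed only
  as the `min_protein_len`/`require_start` hooks.
* **Scaffold concatenation** joins unanchored scaffolds with 100 N
  (configurable; the spacer is recorded in the composite's description)
  and returns a lossless coordinate map.
* **Reported percentages** round half-up to one decimal
  (`round_half_up()`, `percent_of()`); base R's half-to-even would differ
  on exact halves.

## The synthetic-data generator

`generate_truth_set()` builds a reference genotype: non-overlapping genes
(1–6 exons; CDS 300–750 nt split into segments of ≥ 100 nt; introns 22–80
nt; UTRs on both ends; ATG…stop coding sequences free of internal stops)
on a random-background genome (GC 0.36, a typical plant value), two
chromosomes, intergenic gaps of 300–800 nt. `derive_comparison_set()`
realises one planted comparison category per gene:

| category | realisation |
|---|---|
| identical | exact copy |
| query_contained | C-terminal extension of the variant into its own 3′ UTR |
| target_contained | C-terminal truncation (early stop codon written in) |
| binned_match | codon substitutions until the measured identity is within ±2 of the bin centre |
| cds_only_match | compensated double frameshift: DNA ~99% identical, protein scrambled |
| encapsulated_in_utr | CDS rewritten inside a long (700 nt) 3′ UTR of an identical-category host; original locus masked |
| overlaps_5utr / overlaps_3utr | CDS rewritten straddling a host UTR's outer boundary; original locus masked |
| present_no_match | removed from the gene set, genome untouched |
| missing_from_genome | removed and the locus masked with N |

All edits are length-preserving or confined to annotated UTR/intergenic
space. The default category mix (30% identical, 30% binned, 6% + 6%
containments, 5% CDS-only, 13% UTR-related, 5% + 5% present/missing)
keeps every category populated at the default 200 genes; the bin mix
weights high-identity bins the way cross-cultivar comparisons do. Bin
centres (55, 62, 67, …, 97) are chosen so the ±2-point mutation tolerance
cannot leave the planted bin, which is also why recovery tests accept ±1
bin: mutation granularity and end-trimming by local alignment bound the
achievable precision.

`simulate_coverage()` plants support classes per gene and library:
supported genes draw Poisson counts at 8–15 reads/base, low-coverage genes
at 1.5–2.5, unsupported-exon genes additionally have one exon zeroed, and
intergenic background is sparse noise (rate 0.01/base). All planted means
sit at least 1 read/base from the 5 reads/base threshold, so support
recovery is expected to be exact; a planted class that cannot be realised
(an unsupported exon on a single-exon gene) is re-planted as low coverage
and the truth table records what was actually planted.

Everything is deterministic under the config seed (same seed, byte-identical
files).

**What the generator does not emulate** — and hence what passing recovery
tests do *not* show about real data: sequencing error and read-level
artefacts (coverage is drawn, not aligned), repeats and transposons
(background is i.i.d. random, so spurious placements are rarer than in a
real genome), alternative splicing and UTR introns, splice-site motifs,
codon-usage bias, and the correlated errors of human annotators. The
planted truth exercises the *logic* of the classifiers at study scale; it
cannot validate them against biological mess.

## Problem sizes and runtime

The shipped tests and the acceptance script use 200-gene simulations for
planted-truth recovery, a 100-gene self-comparison, 200 random pairs for
the aligner oracle and 100 random length lists for the assembly-statistics
oracle — sizes chosen so the whole suite runs in a couple of minutes on a
single core while every category, bin and support class stays populated
with double-digit counts.

## Known limitations

* Containment is exact; a single polymorphism downgrades a containment to
  a binned match, exactly as in the published analysis.
* Genome placement reports one best location; a CDS present at several
  near-identical loci (recent tandem duplicates) yields the densest one.
* The UTR-relation rules assume the target annotation's locus spans are
  trustworthy; a truncated target UTR turns `encapsulated_in_utr` into
  `present_no_match`.
* `compare_genesets()` assumes one protein per isoform id in each set;
  choosing representatives for multi-isoform loci is the caller's job
  (`find_tandem_duplicates()` picks the longest-protein isoform).

## A worked run

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1, n_genes = 200)
truth <- generate_truth_set(cfg)
variant <- derive_comparison_set(truth, cfg)

cmp <- compare_genesets(
  gene_set(truth$proteins, truth$cds, truth$models, truth$genome),
  gene_set(variant$proteins, variant$cds, variant$models, variant$genome))
glance(cmp)
autoplot(cmp, "bins")

cov <- simulate_coverage(truth$genome, truth$models, seed = 1)
tags <- quality_tags(truth$models, cov$tracks,
  homology = tibble::tibble(
    model_id = cov$truth_support$isoform_id,
    ref_coverage_fraction = cov$truth_support$ref_coverage_fraction,
    missing_end = cov$truth_support$missing_end))
plot_support_classes(tags, "tag")
```
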