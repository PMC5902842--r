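# Whole-genome placement of coding sequences: exact 15-mer tiles of every
# query (both orientations) are matched against the genome in a single
# Biostrings::matchPDict pass, the densest hit cluster per query defines a
# candidate window, and the window is aligned with the exact local
# aligner. A query is "placed" when the alignment reaches the identity and
# query-coverage thresholds; affine gaps let the alignment step across
# short introns, so spliced placements of multi-exon coding sequences are
# still found.

PLACE_TILE <- 15L
PLACE_STEP <- 5L

query_tiles <- function(residues) {
  n <- nchar(residues)
  if (n < PLACE_TILE) return(character(0))
  starts <- unique(c(seq(1L, n - PLACE_TILE + 1L, by = PLACE_STEP),
    n - PLACE_TILE + 1L))
  tiles <- substring(residues, starts, starts + PLACE_TILE - 1L)
  tiles[!grepl("N", tiles, fixed = TRUE)]
}

densest_cluster <- function(pos, max_gap = 2000) {
  pos <- sort(pos)
  grp <- cumsum(c(0L, diff(pos) > max_gap))
  tab <- table(grp)
  best <- names(tab)[which.max(tab)]
  pos[grp == as.integer(best)]
}

#' Place coding sequences on a genome
#'
#' @param queries sequence table of (spliced) coding sequences.
#' @param genome sequence table of genome sequences.
#' @param min_identity minimum percent identity over the aligned span for
#'   a placement to count (default 90).
#' @param min_coverage minimum fraction of the query covered by the
#'   aligned span (default 0.5).
#' @return tibble with one row per query: `query_id`, `placed`, `seq_id`,
#'   `strand`, `start`, `end` (0-based half-open genomic span of the
#'   alignment), `identity`, `coverage`. Unplaced queries carry NA
#'   coordinates.
#' @export
place_on_genome <- function(queries, genome, min_identity = 90,
                            min_coverage = 0.5) {
  nq <- nrow(queries)
  # one tile dictionary over all queries and both orientations
  tile_sets <- list()
  tile_owner <- list()
  for (qi in seq_len(nq)) {
    for (orient in c("+", "-")) {
      s <- if (orient == "+") queries$residues[qi] else
        revcomp(queries$residues[qi])
      tl <- query_tiles(s)
      if (length(tl) == 0) next
      key <- paste0(qi, orient)
      tile_sets[[key]] <- tl
      tile_owner[[key]] <- tibble(qi = qi, orient = orient,
        tile_n = length(tl))
    }
  }
  all_tiles <- unlist(tile_sets, use.names = FALSE)
  owners <- bind_rows(tile_owner)
  owner_of <- rep(seq_len(nrow(owners)), owners$tile_n)

  hits <- NULL
  if (length(all_tiles) > 0) {
    pd <- Biostrings::PDict(all_tiles)
    hits <- bind_rows(lapply(seq_len(nrow(genome)), function(si) {
      m <- Biostrings::matchPDict(pd, Biostrings::DNAString(genome$residues[si]))
      starts <- IRanges::start(m)
      lens <- lengths(starts)
      if (sum(lens) == 0) return(NULL)
      tibble(
        tile = rep(seq_along(lens), lens),
        seq_i = si,
        pos = unlist(starts, use.names = FALSE)
      )
    }))
    if (!is.null(hits) && nrow(hits) > 0) {
      hits$owner <- owner_of[hits$tile]
    }
  }

  rows <- purrr::map(seq_len(nq), function(qi) {
    q <- queries$residues[qi]
    qlen <- nchar(q)
    unplaced <- tibble(query_id = queries$id[qi], placed = FALSE,
      seq_id = NA_character_, strand = NA_character_,
      start = NA_integer_, end = NA_integer_,
      identity = NA_real_, coverage = NA_real_)
    best <- NULL
    for (orient in c("+", "-")) {
      oi <- which(owners$qi == qi & owners$orient == orient)
      if (length(oi) == 0 || is.null(hits) || nrow(hits) == 0) next
      h <- hits[hits$owner == oi, ]
      if (nrow(h) == 0) next
      counts <- table(h$seq_i)
      si <- as.integer(names(counts)[which.max(counts)])
      pos <- densest_cluster(h$pos[h$seq_i == si])
      if (length(pos) < 2 && qlen >= 30) next
      glen <- nchar(genome$residues[si])
      w0 <- max(0L, min(pos) - 1L - 200L)
      w1 <- min(glen, max(pos) + qlen + 200L)
      qs <- if (orient == "+") q else revcomp(q)
      window <- substring(genome$residues[si], w0 + 1L, w1)
      al <- local_align(seq_records("q", qs), seq_records("w", window),
        dna_scoring())
      span <- al$query_end - al$query_start
      if (span == 0) next
      cand <- tibble(
        query_id = queries$id[qi], placed = TRUE,
        seq_id = genome$id[si], strand = orient,
        start = w0 + al$target_start, end = w0 + al$target_end,
        identity = 100 * al$matches / span,
        coverage = span / qlen,
        matches = al$matches
      )
      if (is.null(best) || cand$matches > best$matches) best <- cand
    }
    if (is.null(best)) return(unplaced)
    best$placed <- best$identity >= min_identity &&
      best$coverage >= min_coverage
    if (!best$placed) return(unplaced)
    select(best, -"matches")
  })
  bind_rows(rows)
}
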