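# Derivation of the second-genotype gene set from the reference: per gene,
# its planted comparison category is realised by editing the variant
# genome copy and gene models (exact copy, protein truncation/extension,
# point mutation to a target identity bin, frameshift that preserves the
# DNA but scrambles the protein, relocation of the CDS into another
# gene's UTR, deletion with genome masking, or removal from the gene set
# only). All edits are length-preserving or confined to annotated UTR and
# intergenic space, so coordinates remain comparable across the pair.

str_overwrite <- function(s, start0, replacement) {
  substr(s, start0 + 1, start0 + nchar(replacement)) <- replacement
  s
}

# write a spliced sequence back into genomic intervals (genomic order)
write_spliced <- function(s, ivs, strand, spliced) {
  forward <- if (strand == "+") spliced else revcomp(spliced)
  lens <- ivs$end - ivs$start
  stopifnot(nchar(forward) == sum(lens))
  off <- cumsum(c(0L, lens[-length(lens)]))
  for (j in seq_len(nrow(ivs))) {
    s <- str_overwrite(s, ivs$start[j],
      substring(forward, off[j] + 1, off[j] + lens[j]))
  }
  s
}

# shrink or grow a CDS interval set to new_len bases, trimming/extending
# at the transcription 3' end
cds_set_length <- function(ivs, strand, new_len) {
  tx <- if (strand == "+") seq_len(nrow(ivs)) else rev(seq_len(nrow(ivs)))
  lens <- (ivs$end - ivs$start)[tx]
  total <- sum(lens)
  if (new_len > total) {
    grow <- new_len - total
    last <- tx[length(tx)]
    if (strand == "+") {
      ivs$end[last] <- ivs$end[last] + grow
    } else {
      ivs$start[last] <- ivs$start[last] - grow
    }
    return(iv_sort(ivs))
  }
  keep <- list()
  remaining <- new_len
  for (k in seq_along(tx)) {
    j <- tx[k]
    take <- min(remaining, lens[k])
    if (take > 0) {
      if (strand == "+") {
        keep[[length(keep) + 1]] <- iv(ivs$start[j], ivs$start[j] + take)
      } else {
        keep[[length(keep) + 1]] <- iv(ivs$end[j] - take, ivs$end[j])
      }
    }
    remaining <- remaining - take
  }
  iv_sort(bind_rows(keep))
}

#' Point-mutate a CDS to a target protein identity
#'
#' Applies codon substitutions (never creating a stop, never touching the
#' start or stop codon) until the protein percent identity of the mutant
#' against the original — measured with the same local aligner and
#' query-length denominator the comparison cascade uses — lands within
#' two points of the target. Deterministic under `seed`.
#'
#' @param cds dna string (ATG...stop, length divisible by 3).
#' @param target_percent target protein identity in (0, 100].
#' @param seed integer seed.
#' @return list: `cds` (mutated string), `realized` (measured identity).
#' @export
mutate_to_target_identity <- function(cds, target_percent, seed) {
  stopifnot(target_percent > 0, target_percent <= 100)
  if (target_percent == 100) {
    return(list(cds = cds, realized = 100))
  }
  with_seed(child_seed(seed, 7), {
    n_codons <- nchar(cds) %/% 3
    mutable <- 2:(n_codons - 1)
    perm <- sample(mutable)
    current <- codons_of(cds)
    replacements <- vapply(perm, function(p) {
      sample(setdiff(SENSE_CODONS, current[p]), 1)
    }, character(1))
    prot0 <- as.character(translate_cds(cds))
    scoring <- protein_scoring()
    measure <- function(k) {
      cod <- current
      if (k > 0) cod[perm[seq_len(k)]] <- replacements[seq_len(k)]
      mut <- paste(cod, collapse = "")
      prot <- as.character(translate_cds(mut))
      al <- local_align(seq_records("m", prot), seq_records("o", prot0),
        scoring)
      list(cds = mut, id = 100 * al$matches / nchar(prot))
    }
    lo <- 0L
    hi <- length(perm)
    for (iter in 1:30) {
      k <- (lo + hi) %/% 2L
      m <- measure(k)
      if (abs(m$id - target_percent) <= 2) {
        return(list(cds = m$cds, realized = m$id))
      }
      if (m$id > target_percent) lo <- k + 1L else hi <- k - 1L
      if (lo > hi) break
    }
    # fallback: linear scan
    for (k in seq_len(length(perm))) {
      m <- measure(k)
      if (abs(m$id - target_percent) <= 2) {
        return(list(cds = m$cds, realized = m$id))
      }
    }
    abort(sprintf("cannot reach identity %g without creating stop codons",
      target_percent), class = "genesetqc_sim_error")
  })
}

# double frameshift: delete one base early, insert one base late, fix any
# internal stops -- DNA stays ~99% identical, protein is scrambled
frameshift_cds <- function(cds, seed) {
  with_seed(child_seed(seed, 11), {
    L <- nchar(cds)
    body <- substring(cds, 1, L - 3)
    stop_codon <- substring(cds, L - 2, L)
    shifted <- paste0(
      substring(body, 1, 15),
      substring(body, 17, nchar(body)),
      sample(c("A", "C"), 1)
    )
    repeat {
      cand <- paste0(shifted, stop_codon)
      aa <- strsplit(as.character(
        translate_codons(codons_of(cand))), "")[[1]]
      internal <- which(aa[-length(aa)] == "*")
      if (length(internal) == 0) break
      # change the third base of the offending codon; TAx/TGx -> sense
      pos <- 3L * internal[1]
      substr(shifted, pos, pos) <- "C"
    }
    paste0(shifted, stop_codon)
  })
}

#' Derive the second-genotype gene set with planted categories
#'
#' @param truth output of [generate_truth_set()].
#' @param config the same [sim_config()].
#' @return list: `genome`, `models`, `cds`, `proteins` of the variant
#'   genotype, and `truth` (the reference truth table with `variant_id`
#'   and `realized_identity` columns added).
#' @export
derive_comparison_set <- function(truth, config) {
  with_seed(child_seed(config$seed, 2), derive_impl(truth, config))
}

derive_impl <- function(truth, config) {
  gres <- setNames(truth$genome$residues, truth$genome$id)
  models <- truth$models
  tt <- truth$truth
  n <- nrow(tt)
  keep <- rep(TRUE, n)
  realized <- rep(NA_real_, n)

  model_row <- function(iso) which(models$isoform_id == iso)

  mask_locus <- function(gres, m, flank = 50L) {
    sid <- m$seq_id[1]
    lo <- max(0L, m$start[1] - flank)
    hi <- min(nchar(gres[[sid]]), m$end[1] + flank)
    str_overwrite(gres[[sid]], lo, strrep("N", hi - lo))
  }

  for (i in seq_len(n)) {
    cat_i <- tt$category[i]
    mi <- model_row(tt$isoform_id[i])
    m <- models[mi, ]
    sid <- m$seq_id[1]
    if (cat_i == "identical_equal_length") next

    if (cat_i == "binned_match") {
      s <- extract_spliced(seq_records(sid, gres[[sid]]), sid,
        m$cds[[1]], m$strand[1])
      res <- mutate_to_target_identity(s, tt$target_identity[i],
        child_seed(config$seed, 100 + i))
      gres[[sid]] <- write_spliced(gres[[sid]], m$cds[[1]], m$strand[1],
        res$cds)
      realized[i] <- res$realized
      next
    }

    if (cat_i == "cds_only_match") {
      s <- extract_spliced(seq_records(sid, gres[[sid]]), sid,
        m$cds[[1]], m$strand[1])
      s2 <- frameshift_cds(s, child_seed(config$seed, 200 + i))
      gres[[sid]] <- write_spliced(gres[[sid]], m$cds[[1]], m$strand[1], s2)
      next
    }

    if (cat_i == "target_contained") {
      # C-terminal truncation of the variant: new stop codon k codons early
      s <- extract_spliced(seq_records(sid, gres[[sid]]), sid,
        m$cds[[1]], m$strand[1])
      n_codons <- nchar(s) %/% 3
      k <- sample(5:15, 1)
      new_codons <- n_codons - k
      s2 <- paste0(substring(s, 1, 3 * (new_codons - 1)), "TAA")
      new_iv <- cds_set_length(m$cds[[1]], m$strand[1], 3L * new_codons)
      gres[[sid]] <- write_spliced(gres[[sid]], new_iv, m$strand[1], s2)
      models$cds[[mi]] <- new_iv
      next
    }

    if (cat_i == "query_contained") {
      # C-terminal extension of the variant into its own 3' UTR
      s <- extract_spliced(seq_records(sid, gres[[sid]]), sid,
        m$cds[[1]], m$strand[1])
      mext <- sample(5:12, 1)
      s2 <- paste0(
        substring(s, 1, nchar(s) - 3), "CAA",
        paste(sample(SENSE_CODONS, mext, replace = TRUE), collapse = ""),
        "TAA")
      new_iv <- cds_set_length(m$cds[[1]], m$strand[1], nchar(s2))
      gres[[sid]] <- write_spliced(gres[[sid]], new_iv, m$strand[1], s2)
      models$cds[[mi]] <- new_iv
      next
    }

    if (cat_i == "present_no_match") {
      keep[i] <- FALSE
      next
    }

    if (cat_i == "missing_from_genome") {
      keep[i] <- FALSE
      gres[[sid]] <- mask_locus(gres, m)
      next
    }

    if (cat_i %in% RELOC_CATEGORIES) {
      keep[i] <- FALSE
      cds_seq <- truth$cds$residues[match(tt$isoform_id[i], truth$cds$id)]
      gres[[sid]] <- mask_locus(gres, m)
      host <- models[model_row(paste0(tt$host_id[i], ".1")), ]
      hsid <- host$seq_id[1]
      L <- nchar(cds_seq)
      if (cat_i == "encapsulated_in_utr") {
        u <- host$utr3[[1]]
        u <- u[which.max(u$end - u$start), ]
        at <- u$start[1] + 20L
      } else if (cat_i == "overlaps_3utr") {
        at <- if (host$strand[1] == "+") host$end[1] - 60L else
          host$start[1] + 60L - L
      } else {  # overlaps_5utr
        at <- if (host$strand[1] == "+") host$start[1] + 30L - L else
          host$end[1] - 30L
      }
      gres[[hsid]] <- str_overwrite(gres[[hsid]], at, cds_seq)
      next
    }
  }

  v_models <- models[models$isoform_id %in% tt$isoform_id[keep], ]
  # fresh identifiers for the second genotype, in reference order
  old_loci <- tt$gene_id[keep]
  new_loci <- setNames(sprintf("gB%04d", which(keep)), old_loci)
  v_models <- v_models |>
    mutate(
      locus_id = unname(new_loci[.data$locus_id]),
      isoform_id = paste0(.data$locus_id, ".1")
    ) |>
    arrange(.data$seq_id, .data$start)
  v_models <- derive_utrs(validate_gene_models(v_models))

  v_genome <- seq_records(names(gres), unname(gres), alphabet = "dna")
  v_cds <- seq_records(
    v_models$isoform_id,
    vapply(seq_len(nrow(v_models)), function(j) {
      model_cds_sequence(v_models[j, ], v_genome)
    }, character(1)),
    alphabet = "dna")
  v_prot <- seq_records(
    v_models$isoform_id,
    vapply(v_cds$residues, function(s) as.character(translate_cds(s)),
      character(1)),
    alphabet = "protein")

  tt$variant_id <- ifelse(keep, paste0(unname(new_loci[tt$gene_id]), ".1"),
    NA_character_)
  tt$realized_identity <- realized

  list(genome = v_genome, models = v_models, cds = v_cds,
    proteins = v_prot, truth = tt)
}
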