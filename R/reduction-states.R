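# Gene-state classification: INTACT < FRAMESHIFT_SLIPPAGE < PSEUDOGENE <
# ABSENT. FRAMESHIFT_SLIPPAGE (a single 1-bp indel in a homopolymer tract,
# correctable by transcriptional slippage) counts as functionally intact.

GENE_STATES <- c("INTACT", "FRAMESHIFT_SLIPPAGE", "PSEUDOGENE", "ABSENT")

# severity used by Dollo reconstruction: slippage frameshifts are treated as
# intact (they are reported as branch annotations, not Dollo states)
state_severity <- function(state) {
  unname(c(INTACT = 0L, FRAMESHIFT_SLIPPAGE = 0L, PSEUDOGENE = 1L,
           ABSENT = 2L)[state])
}

dna_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                           baseOnly = FALSE, type = "DNA")
}

align_dna_global <- function(a, b) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = dna_submat(), gapOpening = 5, gapExtension = 2)
}

aligned_strings <- function(al) {
  list(p = as.character(Biostrings::alignedPattern(al)),
       s = as.character(Biostrings::alignedSubject(al)))
}

# count internal stop codons of a CDS read in its own frame
internal_stops <- function(nt) {
  aa <- translate_cds(nt)
  if (nchar(aa) <= 1) return(0L)
  body <- substr(aa, 1, nchar(aa) - 1)  # terminal stop is fine
  stringr::str_count(body, "\\*")
}

# homopolymer run covering 0-based position pos (looks one base left too,
# for deletions at a run boundary); returns list(base, len)
run_at <- function(nt, pos) {
  chars <- seq_chars(nt)
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  pick <- function(p) {
    if (p < 0 || p >= length(chars)) return(NULL)
    i <- which(ends > p)[1]
    list(base = r$values[i], len = r$lengths[i])
  }
  a <- pick(pos); b <- pick(pos - 1)
  cands <- Filter(Negate(is.null), list(a, b))
  if (!length(cands)) return(list(base = NA_character_, len = 0L))
  cands[[which.max(vapply(cands, function(x) x$len, integer(1)))]]
}

# classify one locus nucleotide sequence against an intact reference.
# The load-bearing signals are frame integrity (length mod 3) and internal
# stop codons - raw DNA alignments of AT-rich, low-complexity genes can
# acquire spurious compensating gap pairs, so alignment indels are only used
# to locate candidate slippage positions and to measure truncation.
# Returns list(state, indel_pos, indel_sign, tract_base, tract_len, ref_pos).
classify_locus <- function(nt, ref_nt, min_tract = 7L, min_coverage = 0.6) {
  blank <- list(indel_pos = NA_integer_, indel_sign = NA_integer_,
                tract_base = NA_character_, tract_len = NA_integer_,
                ref_pos = NA_integer_)
  frame_off <- nchar(nt) %% 3L
  stops <- internal_stops(nt)
  al <- align_dna_global(nt, ref_nt)
  as <- aligned_strings(al)
  pch <- seq_chars(as$p); sch <- seq_chars(as$s)
  statev <- ifelse(pch == "-", 1L, ifelse(sch == "-", 2L, 0L))
  coverage <- sum(statev == 0L) / nchar(ref_nt)

  if (frame_off != 0L || stops > 0L) {
    # try every 1-bp indel block as a slippage candidate: a single tract
    # indel whose conceptual correction yields a stop-free in-frame ORF
    r <- rle(statev)
    block_start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
    blocks <- tibble(type = r$values, len = r$lengths, col = block_start) |>
      filter(.data$type != 0L, .data$len == 1L)
    if (nrow(blocks) && coverage >= min_coverage) {
      runs <- rle(seq_chars(nt))
      run_start <- cumsum(c(0L, runs$lengths[-length(runs$lengths)]))
      tracts <- tibble(base = runs$values, start = run_start,
                       len = runs$lengths) |>
        filter(.data$base %in% c("A", "T"), .data$len >= min_tract)
      for (bi in seq_len(nrow(blocks))) {
        b <- blocks[bi, ]
        qpos <- sum(pch[seq_len(b$col - 1L)] != "-")  # query bases before
        rpos <- sum(sch[seq_len(b$col - 1L)] != "-")
        sign <- if (b$type == 2L) +1L else -1L
        if (!nrow(tracts)) next
        # gap placement floats within homopolymeric context: consider every
        # qualifying tract near the aligned indel position
        d <- pmax(tracts$start - qpos, qpos - (tracts$start + tracts$len), 0)
        near <- which(d <= 20L)
        for (tj in near[order(d[near])]) {
          pos <- tracts$start[tj]
          corrected <- slip_correct(nt, pos, sign)
          if (nchar(corrected) %% 3L == 0L &&
              internal_stops(corrected) == 0L) {
            return(c(list(state = "FRAMESHIFT_SLIPPAGE"),
                     list(indel_pos = as.integer(pos), indel_sign = sign,
                          tract_base = tracts$base[tj],
                          tract_len = as.integer(tracts$len[tj]),
                          ref_pos = as.integer(rpos - (qpos - pos)))))
          }
        }
      }
    }
    return(c(list(state = "PSEUDOGENE"), blank))
  }
  if (coverage < min_coverage) return(c(list(state = "PSEUDOGENE"), blank))
  c(list(state = "INTACT"), blank)
}

# translate a region in all six frames
six_frame_aa <- function(region) {
  frames <- character(0)
  for (s in c(region, revcomp(region))) {
    for (off in 0:2) {
      sub <- substr(s, off + 1, nchar(s))
      if (nchar(sub) >= 3) frames <- c(frames, translate_cds(sub))
    }
  }
  frames[nzchar(frames)]
}

# homology screen of an intergenic region against a reference protein:
# evidence of an eroded gene -> "PSEUDOGENE", none -> "ABSENT"
screen_region <- function(region, ref_aa, min_coverage = 0.6, max_e = 1e-5) {
  if (is.null(region) || nchar(region) < 30) return("ABSENT")
  for (fr in six_frame_aa(region)) {
    hit <- align_proteins(fr, ref_aa)
    if (hit$subject_coverage >= min_coverage && hit$evalue_like < max_e) {
      return("PSEUDOGENE")
    }
  }
  "ABSENT"
}

#' Classify gene states across an ortholog table
#'
#' For every family and genome, assigns one of `INTACT`,
#' `FRAMESHIFT_SLIPPAGE`, `PSEUDOGENE`, `ABSENT`. A locus is compared to an
#' intact reference member of its family (a full-length, stop-free CDS from
#' another genome): a single 1-bp indel inside a polyA/polyT tract of at
#' least `min_tract` bp whose conceptual correction restores a stop-free
#' full-length ORF is a slippage frameshift; two or more frame disruptions,
#' any internal stop not attributable to such an indel, or aligned coverage
#' below `min_coverage` make a pseudogene. A family member missing from the
#' annotation is screened against the corresponding intergenic region
#' (six-frame homology): evidence of an eroded gene yields `PSEUDOGENE`,
#' otherwise `ABSENT`. RNA genes are scored by presence/absence only.
#'
#' @param table an `ortholog_table` from [build_ortholog_table()].
#' @param genomes named list of [genome_record()]s.
#' @param min_tract minimum homopolymer tract length for the slippage rule.
#' @param min_coverage alignment coverage below which a gene is eroded.
#' @param igs_check screen intergenic regions of missing genes for eroded
#'   remnants?
#' @param max_region_len cap on the screened intergenic region length.
#' @return tibble: `family_id`, `genome`, `locus_tag`, `state`, plus
#'   slippage-call details (`indel_pos`, `indel_sign`, `tract_base`,
#'   `tract_len`, `ref_pos`).
#' @export
assign_gene_states <- function(table, genomes, min_tract = 7L,
                               min_coverage = 0.6, igs_check = TRUE,
                               max_region_len = 10000L) {
  gids <- attr(table, "genomes") %||% unique(table$genome)
  wide_locus <- tidyr::pivot_wider(table, id_cols = "family_id",
                                   names_from = "genome",
                                   values_from = "locus_tag")
  wide_kind <- tidyr::pivot_wider(table, id_cols = "family_id",
                                  names_from = "genome",
                                  values_from = "kind")
  fams <- wide_locus$family_id
  seq_of <- function(g, locus) {
    rec <- genomes[[g]]
    feature_seq(rec, which(rec$features$locus_tag == locus))
  }
  skipped <- character(0)
  rows <- lapply(seq_along(fams), function(i) {
    loci <- vapply(gids, function(g) wide_locus[[g]][i], character(1))
    kinds <- vapply(gids, function(g) wide_kind[[g]][i], character(1))
    present <- !is.na(loci)
    is_rna <- present & kinds %in% c("tRNA", "rRNA", "other_RNA")
    base_row <- tibble(family_id = fams[i], genome = gids,
                       locus_tag = loci, state = NA_character_,
                       indel_pos = NA_integer_, indel_sign = NA_integer_,
                       tract_base = NA_character_, tract_len = NA_integer_,
                       ref_pos = NA_integer_)
    if (any(is_rna) || !any(present & kinds == "CDS")) {
      # RNA family (or no CDS member at all): presence/absence only
      base_row$state <- ifelse(present, "INTACT", "ABSENT")
      return(base_row)
    }
    # reference: longest full-length stop-free CDS member
    cands <- which(present & kinds == "CDS")
    cand_seqs <- lapply(cands, function(j) seq_of(gids[j], loci[j]))
    okref <- vapply(cand_seqs, function(s)
      nchar(s) %% 3L == 0L && internal_stops(s) == 0L, logical(1))
    if (!any(okref)) {
      skipped <<- c(skipped, fams[i])
      return(base_row)
    }
    ref_j <- cands[okref][which.max(nchar(unlist(cand_seqs[okref])))]
    ref_nt <- seq_of(gids[ref_j], loci[ref_j])
    ref_aa <- sub("\\*$", "", translate_cds(ref_nt))
    for (j in seq_along(gids)) {
      if (!present[j]) {
        st <- "ABSENT"
        if (igs_check) {
          region <- missing_family_region(table, genomes, gids[j], fams[i],
                                          max_region_len)
          st <- screen_region(region, ref_aa, min_coverage)
        }
        base_row$state[j] <- st
      } else if (kinds[j] == "pseudogene") {
        base_row$state[j] <- "PSEUDOGENE"
      } else {
        cl <- classify_locus(seq_of(gids[j], loci[j]), ref_nt,
                             min_tract, min_coverage)
        base_row$state[j] <- cl$state
        base_row$indel_pos[j] <- cl$indel_pos
        base_row$indel_sign[j] <- cl$indel_sign
        base_row$tract_base[j] <- cl$tract_base
        base_row$tract_len[j] <- cl$tract_len
        base_row$ref_pos[j] <- cl$ref_pos
      }
    }
    base_row
  })
  if (length(skipped)) {
    warning("skipped ", length(skipped),
            " family(ies) with no intact reference member", call. = FALSE)
  }
  out <- bind_rows(rows)
  structure(out, class = c("gene_states", class(out)), genomes = gids)
}

# intergenic region of genome g where family fam would sit: the gap between
# the nearest flanking families present in g (families are ordered by the
# conserved gene order); NULL when no flanks can be found
missing_family_region <- function(table, genomes, g, fam,
                                  max_region_len = 10000L) {
  sub <- table[table$genome == g, ]
  sub <- sub[order(sub$family_id), ]
  i <- match(fam, sub$family_id)
  if (is.na(i)) return(NULL)
  n <- nrow(sub)
  left <- right <- NA_integer_
  for (k in seq_len(n - 1)) {
    j <- ((i - 1 - k) %% n) + 1
    if (!is.na(sub$locus_tag[j])) { left <- j; break }
  }
  for (k in seq_len(n - 1)) {
    j <- ((i - 1 + k) %% n) + 1
    if (!is.na(sub$locus_tag[j])) { right <- j; break }
  }
  if (is.na(left) || is.na(right) || left == right) return(NULL)
  rec <- genomes[[g]]
  f <- rec$features
  le <- f$end[match(sub$locus_tag[left], f$locus_tag)]
  rs <- f$start[match(sub$locus_tag[right], f$locus_tag)]
  len <- genome_length(rec)
  if (is.na(le) || is.na(rs)) return(NULL)
  region <- if (rs >= le) substr(rec$sequence, le + 1, rs)
            else paste0(substr(rec$sequence, le + 1, len),
                        substr(rec$sequence, 1, rs))
  if (nchar(region) > max_region_len) return(NULL)
  region
}

#' Detect slippage frameshifts across an ortholog table
#'
#' Extracts every `FRAMESHIFT_SLIPPAGE` call: a single 1-bp indel inside a
#' homopolymer tract whose conceptual correction restores the reading frame.
#' Calls in different genomes at the same reference-aligned position (within
#' `shared_tol` bp) are annotated as shared - a frameshift inherited from a
#' common ancestor, as for dnaX.
#'
#' @param table an `ortholog_table`.
#' @param genomes named list of [genome_record()]s.
#' @param min_tract minimum tract length for the slippage rule.
#' @param states optional precomputed result of [assign_gene_states()].
#' @param shared_tol tolerance in bp for calling two indel positions shared.
#' @return tibble: `family_id`, `genome`, `locus_tag`, `indel_pos`,
#'   `indel_sign`, `tract_base`, `tract_len`, `ref_pos`, `shared`.
#' @export
detect_slippage_frameshifts <- function(table, genomes, min_tract = 7L,
                                        states = NULL, shared_tol = 10L) {
  states <- states %||% assign_gene_states(table, genomes, min_tract)
  fs <- states |> filter(.data$state == "FRAMESHIFT_SLIPPAGE")
  if (!nrow(fs)) {
    return(tibble(family_id = character(), genome = character(),
                  locus_tag = character(), indel_pos = integer(),
                  indel_sign = integer(), tract_base = character(),
                  tract_len = integer(), ref_pos = integer(),
                  shared = logical()))
  }
  fs |>
    group_by(.data$family_id) |>
    mutate(shared = n() > 1 &
             vapply(seq_len(n()), function(k)
               any(abs(.data$ref_pos[k] - .data$ref_pos[-k]) <= shared_tol &
                     .data$indel_sign[k] == .data$indel_sign[-k]),
               logical(1))) |>
    ungroup() |>
    select("family_id", "genome", "locus_tag", "indel_pos", "indel_sign",
           "tract_base", "tract_len", "ref_pos", "shared")
}
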