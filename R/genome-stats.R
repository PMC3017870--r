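#' Summary statistics for an annotated genome
#'
#' Computes the usual reduced-genome report card: size, GC content, gene
#' counts by kind (pseudogenes tracked separately from the gene total), mean
#' CDS length, median intergenic spacer length and percent coding. Percent
#' coding counts each genomic base covered by at least one gene once (union,
#' not sum).
#'
#' @param rec a [genome_record()].
#' @return a one-row tibble.
#' @export
genome_stats <- function(rec) {
  len <- genome_length(rec)
  chars <- seq_chars(rec$sequence)
  gc <- sum(chars %in% c("G", "C")) / len
  f <- rec$features
  kinds <- table(factor(f$kind, levels = c("CDS", "tRNA", "rRNA", "other_RNA",
                                           "pseudogene")))
  coding_kinds <- f$kind != "pseudogene"
  pct_cov <- function(sub) {
    if (!nrow(sub)) return(0)
    ir <- IRanges::reduce(IRanges::IRanges(sub$start + 1L, sub$end))
    sum(IRanges::width(ir)) / len
  }
  igs <- extract_igs(rec)
  cds <- f[f$kind == "CDS", ]
  tibble(
    id = rec$id,
    size_bp = len,
    gc_fraction = gc,
    total_genes = sum(kinds[c("CDS", "tRNA", "rRNA", "other_RNA")]),
    protein_coding = unname(kinds["CDS"]),
    trna_count = unname(kinds["tRNA"]),
    rrna_count = unname(kinds["rRNA"]),
    other_rna = unname(kinds["other_RNA"]),
    pseudogenes = unname(kinds["pseudogene"]),
    mean_cds_length = if (nrow(cds)) mean(cds$end - cds$start) else NA_real_,
    median_igs_length = if (nrow(igs)) median(igs$length) else NA_real_,
    pct_protein_coding = pct_cov(f[f$kind == "CDS", ]),
    pct_coding_incl_rna = pct_cov(f[coding_kinds, ])
  )
}

#' Extract intergenic spacers (IGS)
#'
#' An IGS is the sequence between adjacent genes (protein-coding, RNA-coding
#' or pseudogene). Abutting genes yield a zero-length record; overlapping
#' gene pairs yield no record. For circular genomes the wrap-around spacer
#' between the last and first feature is included.
#'
#' @param rec a [genome_record()].
#' @return tibble with columns `left_locus`, `right_locus`, `start`, `end`
#'   (0-based half-open; `end` may exceed genome length for the wrap-around
#'   spacer), `length` and `spans_missing` (filled by downstream analysis).
#' @export
extract_igs <- function(rec) {
  f <- rec$features
  out <- tibble(left_locus = character(), right_locus = character(),
                start = integer(), end = integer(), length = integer(),
                spans_missing = NA)
  if (nrow(f) < 2L) return(out[0, ])
  len <- genome_length(rec)
  # running maximum end handles nested features: the left flank of a gap is
  # whichever feature reaches furthest right
  rows <- list()
  run_end <- f$end[1]
  run_locus <- f$locus_tag[1]
  for (i in 2:nrow(f)) {
    if (f$start[i] >= run_end) {
      rows[[length(rows) + 1L]] <- tibble(
        left_locus = run_locus, right_locus = f$locus_tag[i],
        start = run_end, end = f$start[i],
        length = f$start[i] - run_end)
    }
    if (f$end[i] > run_end) { run_end <- f$end[i]; run_locus <- f$locus_tag[i] }
  }
  if (rec$is_circular) {
    gap <- len - run_end + f$start[1]
    if (gap >= 0 && f$start[1] >= 0 && run_end <= len) {
      rows[[length(rows) + 1L]] <- tibble(
        left_locus = run_locus, right_locus = f$locus_tag[1],
        start = run_end, end = run_end + gap, length = gap)
    }
  }
  if (!length(rows)) return(out[0, ])
  mutate(bind_rows(rows), spans_missing = NA)
}

#' Extract IGS sequences
#'
#' @param rec a [genome_record()].
#' @param igs tibble from [extract_igs()]; extracted afresh when `NULL`.
#' @return `igs` with a `sequence` column (wrap-around spacers read through
#'   the origin).
#' @export
igs_sequences <- function(rec, igs = NULL) {
  igs <- igs %||% extract_igs(rec)
  len <- genome_length(rec)
  igs$sequence <- vapply(seq_len(nrow(igs)), function(i) {
    if (igs$end[i] <= len) region_seq(rec, igs$start[i], igs$end[i])
    else paste0(region_seq(rec, igs$start[i], len),
                region_seq(rec, 0L, igs$end[i] - len))
  }, character(1))
  igs
}

#' Write IGS records as BED
#'
#' @param igs tibble from [extract_igs()].
#' @param rec the source [genome_record()] (for the chromosome name).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_igs_bed <- function(igs, rec, path) {
  bed <- data.frame(chrom = rec$id, start = igs$start, end = igs$end,
                    name = paste0(igs$left_locus, "|", igs$right_locus))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extend a candidate ORF to its start and stop codons
#'
#' Given a homology-defined region, moves the start to the closest in-frame
#' upstream ATG and the end to the first in-frame stop codon downstream
#' (strand-aware). Coordinates already bounded by ATG/stop are unchanged.
#'
#' @param rec a [genome_record()].
#' @param start,end 0-based half-open region coordinates.
#' @param strand `"+"` or `"-"`.
#' @param max_search search limit in bp for each extension.
#' @return a list with `start`, `end`, `found_start`, `found_stop`; when no
#'   in-frame ATG/stop is found within `max_search` the corresponding
#'   coordinate is unchanged and the flag is `FALSE`.
#' @export
extend_orf <- function(rec, start, end, strand = "+", max_search = 3000L) {
  len <- genome_length(rec)
  codon_at <- function(pos) substr(rec$sequence, pos + 1L, pos + 3L)
  if (strand == "+") {
    s <- start; found_start <- FALSE
    while (s >= 0 && start - s <= max_search) {
      if (codon_at(s) == "ATG") { found_start <- TRUE; break }
      s <- s - 3L
    }
    if (!found_start) s <- start
    e <- end; found_stop <- FALSE
    if (codon_at(e - 3L) %in% STOP_CODONS) {
      found_stop <- TRUE
    } else {
      while (e + 3L <= len && e - end <= max_search) {
        if (codon_at(e) %in% STOP_CODONS) { e <- e + 3L; found_stop <- TRUE; break }
        e <- e + 3L
      }
      if (!found_stop) e <- end
    }
    list(start = s, end = e, found_start = found_start, found_stop = found_stop)
  } else {
    # mirror: start codon lies at the high-coordinate end
    rc_codon <- function(pos) revcomp(substr(rec$sequence, pos - 2L, pos))
    e <- end; found_start <- FALSE
    while (e <= len && e - end <= max_search) {
      if (rc_codon(e) == "ATG") { found_start <- TRUE; break }
      e <- e + 3L
    }
    if (!found_start) e <- end
    s <- start; found_stop <- FALSE
    if (rc_codon(s + 3L) %in% STOP_CODONS) {
      found_stop <- TRUE
    } else {
      while (s - 3L >= 0 && start - s <= max_search) {
        if (rc_codon(s) %in% STOP_CODONS) { s <- s - 3L; found_stop <- TRUE; break }
        s <- s - 3L
      }
      if (!found_stop) s <- start
    }
    list(start = s, end = e, found_start = found_start, found_stop = found_stop)
  }
}
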