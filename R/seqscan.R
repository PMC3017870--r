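#' Find maximal homopolymer tracts
#'
#' Returns all maximal runs of a single base with length at least `min_len`.
#' Homopolymeric tracts (especially polyA/polyT in AT-rich endosymbiont
#' genomes) are hotspots for replication and transcription slippage.
#'
#' @param seq nucleotide string.
#' @param bases which bases to report runs of (default polyA/polyT).
#' @param min_len minimum run length in bp (>= 2).
#' @return tibble with `base`, `start` (0-based) and `length`, sorted by start.
#' @export
find_homopolymers <- function(seq, bases = c("A", "T"), min_len = 9L) {
  stopifnot(min_len >= 2L)
  r <- rle(seq_chars(toupper(seq)))
  starts <- cumsum(c(0L, r$lengths[-length(r$lengths)]))
  keep <- r$values %in% bases & r$lengths >= min_len
  tibble(base = r$values[keep], start = starts[keep],
         length = r$lengths[keep])
}

#' Homopolymer tracts inside protein-coding genes
#'
#' Finds long homopolymer tracts lying entirely within annotated CDS. With
#' `strand = "coding"` (default) the scan is for polyA runs on the coding
#' strand of each CDS, so a genomic polyT run inside a minus-strand gene
#' counts as a coding-strand polyA: slippage operates on the transcribed
#' strand. With `strand = "genomic"` both polyA and polyT runs on the genomic
#' forward strand are counted when fully inside a CDS.
#'
#' @param rec a [genome_record()].
#' @param min_len minimum tract length in bp.
#' @param strand counting convention, `"coding"` or `"genomic"`.
#' @return tibble with `containing_locus`, `base`, `start` (genomic, 0-based),
#'   `length`.
#' @export
cds_homopolymer_tracts <- function(rec, min_len = 9L,
                                   strand = c("coding", "genomic")) {
  strand <- match.arg(strand)
  cds <- rec$features[rec$features$kind == "CDS", ]
  if (!nrow(cds)) {
    return(tibble(containing_locus = character(), base = character(),
                  start = integer(), length = integer()))
  }
  if (strand == "coding") {
    rows <- lapply(seq_len(nrow(cds)), function(i) {
      s <- region_seq(rec, cds$start[i], cds$end[i], cds$strand[i])
      tr <- find_homopolymers(s, bases = "A", min_len = min_len)
      if (!nrow(tr)) return(NULL)
      gstart <- if (cds$strand[i] == "+") cds$start[i] + tr$start
                else cds$end[i] - tr$start - tr$length
      tibble(containing_locus = cds$locus_tag[i], base = tr$base,
             start = as.integer(gstart), length = tr$length)
    })
    out <- bind_rows(rows[!vapply(rows, is.null, logical(1))])
  } else {
    tr <- find_homopolymers(rec$sequence, bases = c("A", "T"), min_len = min_len)
    if (!nrow(tr)) return(tibble(containing_locus = character(),
                                 base = character(), start = integer(),
                                 length = integer()))
    hit <- vapply(seq_len(nrow(tr)), function(i) {
      j <- which(cds$start <= tr$start[i] & cds$end >= tr$start[i] + tr$length[i])
      if (length(j)) cds$locus_tag[j[1]] else NA_character_
    }, character(1))
    out <- mutate(tr, containing_locus = hit)[!is.na(hit),
                                              c("containing_locus", "base",
                                                "start", "length")]
  }
  if (!nrow(out)) return(tibble(containing_locus = character(),
                                base = character(), start = integer(),
                                length = integer()))
  arrange(out, .data$start)
}

#' Count long homopolymer tracts in coding regions
#'
#' @inheritParams cds_homopolymer_tracts
#' @return integer count of tracts fully inside CDS.
#' @export
count_long_tracts_in_cds <- function(rec, min_len = 9L,
                                     strand = c("coding", "genomic")) {
  nrow(cds_homopolymer_tracts(rec, min_len, strand))
}

#' Sliding-window GC content and GC skew profile
#'
#' GC skew of a window is (G - C)/(G + C); windows with G + C = 0 are
#' recorded as 0 and flagged. The cumulative skew is the running sum of
#' per-window skews; for a circular genome its global minimum marks the
#' replication origin and its maximum the terminus when the leading strand
#' is G-rich.
#'
#' @param seq nucleotide string or a [genome_record()].
#' @param window window size in bp.
#' @param step step size in bp.
#' @param circular wrap windows around the end? Defaults to the record's
#'   topology when `seq` is a [genome_record()], else `TRUE`.
#' @return tibble of class `skew_profile` with `center`, `gc_content`,
#'   `gc_skew`, `cumulative_skew`, `undefined` (zero-GC flag); window/step
#'   metadata kept as attributes.
#' @export
gc_profile <- function(seq, window = 1000L, step = 10L, circular = NULL) {
  if (inherits(seq, "genome_record")) {
    circular <- circular %||% seq$is_circular
    seq <- seq$sequence
  }
  circular <- circular %||% TRUE
  len <- nchar(seq)
  if (window > len) stop("window larger than sequence", call. = FALSE)
  chars <- seq_chars(toupper(seq))
  if (circular) {
    chars_ext <- c(chars, chars[seq_len(window - 1L)])
    starts <- seq.int(0L, len - 1L, by = step)
  } else {
    chars_ext <- chars
    starts <- seq.int(0L, len - window, by = step)
  }
  cg <- cumsum(chars_ext == "G")
  cc <- cumsum(chars_ext == "C")
  g <- cg[starts + window] - c(0L, cg)[starts + 1L]
  c_ <- cc[starts + window] - c(0L, cc)[starts + 1L]
  denom <- g + c_
  skew <- ifelse(denom == 0, 0, (g - c_) / denom)
  out <- tibble(
    center = (starts + window / 2) %% len,
    gc_content = denom / window,
    gc_skew = skew,
    cumulative_skew = cumsum(skew),
    undefined = denom == 0
  )
  structure(out, class = c("skew_profile", class(out)),
            window = window, step = step, genome_length = len,
            circular = circular)
}

#' Predict the replication origin from cumulative GC skew
#'
#' The origin is called at the global minimum of the (detrended) cumulative
#' skew and the terminus at the maximum, the convention when the leading
#' strand is G-rich; the symmetric arrangement of extrema makes the call
#' orientation-free. The call is confident only when the mean-skew contrast
#' between the two replichores clears both an absolute floor and four
#' standard errors estimated from non-overlapping windows.
#'
#' @param profile a `skew_profile` from [gc_profile()].
#' @param rec optional [genome_record()] used to report the genes flanking
#'   the origin.
#' @param min_amplitude absolute floor for the per-replichore mean skew.
#' @return one-row tibble: `origin_pos`, `terminus_pos`, `confident`,
#'   `amplitude`, `flank_left`, `flank_right`, `method`.
#' @export
predict_origin <- function(profile, rec = NULL, min_amplitude = 0.01) {
  n <- nrow(profile)
  cum <- profile$cumulative_skew
  idx <- seq_len(n)
  detr <- cum - idx / n * cum[n]
  i_min <- which.min(detr)
  i_max <- which.max(detr)
  origin_pos <- profile$center[i_min]
  terminus_pos <- profile$center[i_max]
  # replichore arcs by window index (circular)
  if (i_min < i_max) arc1 <- (i_min + 1L):i_max else arc1 <- c(seq_len(i_max), if (i_min < n) (i_min + 1L):n)
  arc2 <- setdiff(idx, arc1)
  stride <- max(1L, attr(profile, "window") %/% attr(profile, "step"))
  sub1 <- profile$gc_skew[arc1[seq(1L, length(arc1), by = stride)]]
  sub2 <- profile$gc_skew[arc2[seq(1L, length(arc2), by = stride)]]
  delta <- mean(profile$gc_skew[arc1]) - mean(profile$gc_skew[arc2])
  se <- sqrt(stats::var(sub1) / max(1, length(sub1)) +
             stats::var(sub2) / max(1, length(sub2)))
  amplitude <- abs(delta) / 2
  confident <- length(sub1) > 2 && length(sub2) > 2 && !is.na(se) &&
    amplitude >= max(min_amplitude, 4 * se)
  fl <- c(NA_character_, NA_character_)
  if (!is.null(rec) && nrow(rec$features)) {
    f <- rec$features
    nm <- ifelse(nzchar(f$gene_name), f$gene_name, f$locus_tag)
    left <- which(f$end <= origin_pos)
    right <- which(f$start >= origin_pos)
    fl[1] <- if (length(left)) nm[left[which.max(f$end[left])]] else nm[which.max(f$end)]
    fl[2] <- if (length(right)) nm[right[which.min(f$start[right])]] else nm[which.min(f$start)]
    inside <- which(f$start <= origin_pos & f$end > origin_pos)
    if (length(inside)) fl <- rep(nm[inside[1]], 2)
  }
  tibble(origin_pos = origin_pos, terminus_pos = terminus_pos,
         confident = confident, amplitude = amplitude,
         flank_left = fl[1], flank_right = fl[2],
         method = "cumulative_skew_extremum")
}

#' Find dnaA boxes
#'
#' Scans both strands for an IUPAC consensus motif (default TTWTNCACA, the
#' canonical dnaA box). Positions are 0-based on the forward strand.
#'
#' @param seq nucleotide string or [genome_record()].
#' @param pattern IUPAC motif.
#' @return tibble `start`, `strand`, `matched_text` (forward-strand text).
#' @export
find_dnaa_boxes <- function(seq, pattern = "TTWTNCACA") {
  if (inherits(seq, "genome_record")) seq <- seq$sequence
  pattern <- toupper(pattern)
  ok <- strsplit(pattern, "")[[1]] %in% names(Biostrings::IUPAC_CODE_MAP)
  if (!all(ok)) stop("invalid IUPAC letter in pattern", call. = FALSE)
  subject <- Biostrings::DNAString(seq)
  fwd <- Biostrings::matchPattern(pattern, subject, fixed = FALSE)
  rev <- Biostrings::matchPattern(revcomp(pattern), subject, fixed = FALSE)
  out <- bind_rows(
    tibble(start = Biostrings::start(fwd) - 1L, strand = "+",
           matched_text = as.character(fwd)),
    tibble(start = Biostrings::start(rev) - 1L, strand = "-",
           matched_text = as.character(rev))
  )
  arrange(out, .data$start)
}

#' Cluster motif hits
#'
#' Reports windows containing at least `min_count` hits, merging overlapping
#' windows. Used to ask whether a genome shows the dense dnaA-box cluster
#' typical of bacterial origins.
#'
#' @param hits tibble from [find_dnaa_boxes()].
#' @param window window size in bp.
#' @param min_count minimum hits per window.
#' @return tibble `start`, `end`, `n_hits` of merged cluster regions.
#' @export
cluster_dnaa_boxes <- function(hits, window = 300L, min_count = 4L) {
  empty <- tibble(start = integer(), end = integer(), n_hits = integer())
  if (!nrow(hits)) return(empty)
  s <- sort(hits$start)
  cnt <- vapply(s, function(x) sum(s >= x & s < x + window), integer(1))
  anchors <- s[cnt >= min_count]
  if (!length(anchors)) return(empty)
  ir <- IRanges::reduce(IRanges::IRanges(anchors, anchors + window - 1L))
  tibble(start = IRanges::start(ir), end = IRanges::end(ir) + 1L,
         n_hits = vapply(seq_along(ir), function(i)
           sum(s >= IRanges::start(ir)[i] & s < IRanges::end(ir)[i] + 1L),
           integer(1)))
}
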