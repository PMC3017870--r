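#' Find inverted-repeat palindromes
#'
#' EMBOSS-style search for inverted repeats: two arms of equal length
#' (`min_arm`-`max_arm` bp), the second the reverse complement of the first
#' up to `max_mismatch` substitutions, separated by a gap of at most
#' `max_gap` bp. Arms are maximal (not extendable inward or outward) and
#' their innermost/outermost base pairs always match. With
#' `suppress = TRUE`, overlapping hits are reduced to a non-redundant set
#' keeping the longest arm (ties: fewer mismatches, then leftmost).
#'
#' @param seq nucleotide string or [genome_record()].
#' @param min_arm,max_arm arm length bounds in bp.
#' @param max_gap maximum gap between arms in bp.
#' @param max_mismatch maximum substitutions between arm2 and the reverse
#'   complement of arm1.
#' @param suppress drop overlapping/nested sub-hits?
#' @param rec optional [genome_record()] used to classify each hit against
#'   the annotation (`fully_igs`, `partial_igs`, `genic`). When `seq` is a
#'   `genome_record` it is used automatically.
#' @return tibble: `arm1_start`, `arm2_start` (0-based), `arm_length`, `gap`,
#'   `mismatches`, `start`, `end` (span, half-open), `span`, and
#'   `igs_overlap` when an annotation is available.
#' @export
find_palindromes <- function(seq, min_arm = 30L, max_arm = 1000L,
                             max_gap = 20L, max_mismatch = 3L,
                             suppress = TRUE, rec = NULL) {
  stopifnot(min_arm > 0, max_arm >= min_arm, max_gap >= 0, max_mismatch >= 0)
  if (inherits(seq, "genome_record")) {
    rec <- rec %||% seq
    seq <- seq$sequence
  }
  code <- c(A = 0L, C = 1L, G = 2L, T = 3L, N = 4L)
  x <- unname(code[seq_chars(toupper(seq))])
  m <- .palindrome_scan(x, as.integer(min_arm), as.integer(max_arm),
                        as.integer(max_gap), as.integer(max_mismatch))
  out <- tibble(arm1_start = unname(m[, 1]), arm2_start = unname(m[, 2]),
                arm_length = unname(m[, 3]), gap = unname(m[, 4]),
                mismatches = unname(m[, 5])) |>
    mutate(start = .data$arm1_start,
           end = .data$arm2_start + .data$arm_length,
           span = 2L * .data$arm_length + .data$gap)
  if (suppress && nrow(out) > 1) out <- suppress_palindromes(out)
  if (!is.null(rec) && nrow(out)) {
    out$igs_overlap <- classify_igs_overlap(rec, out$start, out$end)
  }
  out
}

# non-redundant set: keep longest arm, ties by fewer mismatches then leftmost
suppress_palindromes <- function(hits) {
  hits <- arrange(hits, dplyr::desc(.data$arm_length), .data$mismatches,
                  .data$start)
  kept <- logical(nrow(hits))
  ends <- integer(0); starts <- integer(0)
  for (i in seq_len(nrow(hits))) {
    if (!any(hits$start[i] < ends & hits$end[i] > starts)) {
      kept[i] <- TRUE
      starts <- c(starts, hits$start[i]); ends <- c(ends, hits$end[i])
    }
  }
  arrange(hits[kept, ], .data$start)
}

# classify spans against the gene annotation
classify_igs_overlap <- function(rec, start, end) {
  f <- rec$features
  if (!nrow(f)) return(rep("fully_igs", length(start)))
  genes <- IRanges::reduce(IRanges::IRanges(f$start + 1L, f$end))
  covered <- vapply(seq_along(start), function(i) {
    sum(IRanges::width(IRanges::intersect(
      genes, IRanges::IRanges(start[i] + 1L, end[i]))))
  }, numeric(1))
  width <- end - start
  dplyr::case_when(covered == 0 ~ "fully_igs",
                   covered == width ~ "genic",
                   TRUE ~ "partial_igs")
}
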