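#' Construct a genome record
#'
#' A `genome_record` bundles a (usually circular) genome sequence with its
#' typed, stranded gene features. All coordinates are 0-based half-open;
#' GenBank I/O converts at the boundary.
#'
#' @param id genome identifier.
#' @param sequence nucleotide string over A/C/G/T/N.
#' @param features tibble with columns `locus_tag`, `gene_name`, `kind`
#'   (one of `"CDS"`, `"tRNA"`, `"rRNA"`, `"other_RNA"`, `"pseudogene"`),
#'   `start`, `end` (0-based half-open), `strand` (`"+"`/`"-"`) and an
#'   optional list-column `frameshift_positions`. Rows are sorted by `start`.
#' @param is_circular logical; is the genome circular?
#' @return an object of class `genome_record`.
#' @export
genome_record <- function(id, sequence, features = empty_features(),
                          is_circular = TRUE) {
  sequence <- toupper(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0L)
  check_alphabet(sequence, paste0("genome '", id, "'"))
  features <- as_tibble(features)
  if (!"frameshift_positions" %in% names(features)) {
    features$frameshift_positions <- rep(list(integer(0)), nrow(features))
  }
  if (!"gene_name" %in% names(features)) features$gene_name <- ""
  req <- c("locus_tag", "gene_name", "kind", "start", "end", "strand")
  missing_cols <- setdiff(req, names(features))
  if (length(missing_cols)) {
    stop("features is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  features <- features[, c(req, "frameshift_positions")]
  len <- nchar(sequence)
  if (nrow(features)) {
    stopifnot(all(features$start < features$end),
              all(features$start >= 0L), all(features$end <= len),
              all(features$strand %in% c("+", "-")),
              all(features$kind %in% c("CDS", "tRNA", "rRNA", "other_RNA",
                                       "pseudogene")))
    features <- arrange(features, .data$start, .data$end)
  }
  structure(list(id = id, sequence = sequence, is_circular = is_circular,
                 features = features),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record> ", x$id, ": ", format(nchar(x$sequence), big.mark = ","),
      " bp, ", if (x$is_circular) "circular" else "linear", ", ",
      nrow(x$features), " features\n", sep = "")
  invisible(x)
}

# empty feature table with the canonical columns
empty_features <- function() {
  tibble(locus_tag = character(), gene_name = character(), kind = character(),
         start = integer(), end = integer(), strand = character(),
         frameshift_positions = list())
}

genome_length <- function(rec) nchar(rec$sequence)

#' Extract the (strand-aware) sequence of a region
#'
#' @param rec a [genome_record()].
#' @param start,end 0-based half-open coordinates.
#' @param strand `"+"` or `"-"`; minus returns the reverse complement.
#' @return character scalar.
#' @export
region_seq <- function(rec, start, end, strand = "+") {
  s <- substr(rec$sequence, start + 1L, end)
  if (strand == "-") s <- revcomp(s)
  s
}

# coding-strand sequence of feature row i
feature_seq <- function(rec, i) {
  f <- rec$features[i, ]
  region_seq(rec, f$start, f$end, f$strand)
}

#' Rotate a circular genome so that `offset` becomes position 0
#'
#' Feature coordinates are shifted accordingly; features that would span the
#' new origin are not allowed (choose an offset in an intergenic gap).
#'
#' @param rec a circular [genome_record()].
#' @param offset 0-based position that becomes the new position 0.
#' @return a rotated `genome_record` with attribute `rotation_offset`.
#' @export
rotate_genome <- function(rec, offset) {
  stopifnot(rec$is_circular)
  len <- genome_length(rec)
  offset <- offset %% len
  if (offset == 0L) return(rec)
  newseq <- paste0(substr(rec$sequence, offset + 1L, len),
                   substr(rec$sequence, 1L, offset))
  f <- rec$features
  if (nrow(f)) {
    ns <- (f$start - offset) %% len
    ne <- ns + (f$end - f$start)
    if (any(ne > len)) stop("rotation offset splits a feature; pick a gap")
    f$start <- as.integer(ns); f$end <- as.integer(ne)
    f$frameshift_positions <- lapply(f$frameshift_positions,
                                     function(p) as.integer((p - offset) %% len))
  }
  out <- genome_record(rec$id, newseq, f, rec$is_circular)
  attr(out, "rotation_offset") <- offset
  out
}
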