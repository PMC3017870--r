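#' @importFrom rlang %||% .data
#' @importFrom dplyr mutate filter select arrange bind_rows group_by summarise ungroup left_join n row_number
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_chr map_int map_dbl map_lgl map2 pmap imap keep
#' @importFrom stats median rbinom runif rnorm setNames pnorm sd quantile
#' @importFrom utils head tail combn
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA sequences (A/C/G/T/N, case-insensitive).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# split a sequence string into a character vector of single bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# translate a CDS (character string, coding strand); incomplete terminal
# codons are dropped; stops rendered as "*"
translate_cds <- function(nt) {
  n <- nchar(nt) - nchar(nt) %% 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1L, n)),
    if.fuzzy.codon = "solve", no.init.codon = TRUE
  ))
}

# shortest distance between two positions on a circle of length len
circular_dist <- function(a, b, len) {
  d <- abs(a - b) %% len
  pmin(d, len - d)
}

# validate a bare DNA alphabet (N allowed, other ambiguity codes rejected)
check_alphabet <- function(seq, where = "sequence") {
  bad <- gsub("[ACGTN]", "", toupper(seq))
  if (any(nchar(bad) > 0)) {
    stop(where, " contains characters outside {A,C,G,T,N}: ",
         paste(unique(seq_chars(paste(bad, collapse = ""))), collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}
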