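#' Read a GenBank flat file into a genome record
#'
#' Parses a GenBank flat file (LOCUS, FEATURES, ORIGIN). GenBank 1-based
#' inclusive coordinates are converted to 0-based half-open; `complement()`
#' sets the strand and `join()` locations are normalized to their enclosing
#' span. Features that wrap around the origin of a circular genome are
#' normalized by rotating the sequence so that no feature spans position 0
#' (the rotation offset is recorded in attribute `rotation_offset`).
#'
#' Feature keys are typed as: `CDS` (or `pseudogene` when `/pseudo` is set),
#' `tRNA`, `rRNA`, and `ncRNA`/`misc_RNA`/`tmRNA` as `other_RNA`. `source` and
#' `gene` keys are structural and skipped silently; any other key is skipped
#' with a warning.
#'
#' @param path path to a GenBank flat file.
#' @return a [genome_record()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  id <- "genome"
  is_circular <- FALSE
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus)) {
    toks <- strsplit(trimws(locus[1]), "\\s+")[[1]]
    if (length(toks) >= 2) id <- toks[2]
    is_circular <- grepl("circular", locus[1], ignore.case = TRUE)
  }

  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("GenBank record has no ORIGIN sequence", call. = FALSE)
  endrec <- grep("^//", lines)
  endrec <- if (length(endrec)) endrec[endrec > ori[1]][1] else length(lines) + 1L
  seq_lines <- lines[(ori[1] + 1L):(endrec - 1L)]
  sequence <- toupper(gsub("[0-9 \t]", "", paste(seq_lines, collapse = "")))
  if (!nchar(sequence)) stop("GenBank record has no ORIGIN sequence", call. = FALSE)
  check_alphabet(sequence, path)
  len <- nchar(sequence)

  feat_start <- grep("^FEATURES", lines)
  rows <- list()
  skipped <- character(0)
  if (length(feat_start)) {
    block <- lines[(feat_start[1] + 1L):(ori[1] - 1L)]
    cur <- NULL
    flush <- function(cur) {
      if (is.null(cur)) return(NULL)
      key <- cur$key
      if (key %in% c("source", "gene")) return(NULL)
      kind <- switch(key,
                     CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                     ncRNA = , misc_RNA = , tmRNA = "other_RNA",
                     NA_character_)
      if (is.na(kind)) { skipped <<- c(skipped, key); return(NULL) }
      if (isTRUE(cur$pseudo)) kind <- "pseudogene"
      loc <- parse_gb_location(cur$loc, len)
      tibble(locus_tag = cur$locus_tag %||% "", gene_name = cur$gene %||% "",
             kind = kind, start = loc$start, end = loc$end, strand = loc$strand,
             frameshift_positions = list(cur$fs %||% integer(0)),
             wrap = loc$wrap, end_width = loc$end_width)
    }
    for (ln in block) {
      key <- trimws(substr(ln, 1, 20))
      body <- trimws(substr(ln, 21, nchar(ln)))
      if (nzchar(key)) {
        rows[[length(rows) + 1L]] <- flush(cur)
        cur <- list(key = key, loc = body, pseudo = FALSE)
      } else if (!is.null(cur)) {
        if (startsWith(body, "/")) {
          q <- sub("^/", "", body)
          if (grepl("^locus_tag=", q)) cur$locus_tag <- gsub('"', "", sub("^locus_tag=", "", q))
          else if (grepl("^gene=", q)) cur$gene <- gsub('"', "", sub("^gene=", "", q))
          else if (q == "pseudo") cur$pseudo <- TRUE
          else if (grepl("^note=.*frameshift_positions:", q)) {
            nums <- sub('.*frameshift_positions:([0-9,]+).*', "\\1", q)
            cur$fs <- as.integer(strsplit(nums, ",")[[1]])
          }
        } else {
          cur$loc <- paste0(cur$loc, body)  # continued location line
        }
      }
    }
    rows[[length(rows) + 1L]] <- flush(cur)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(skipped)) {
    warning("skipped unknown feature keys: ",
            paste(unique(skipped), collapse = ", "), call. = FALSE)
  }
  feats <- if (length(rows)) bind_rows(rows) else
    mutate(empty_features(), wrap = logical(0), end_width = integer(0))

  rotation <- 0L
  if (nrow(feats) && any(feats$wrap)) {
    rotation <- as.integer(min(feats$start[feats$wrap]))
    feats$start <- as.integer((feats$start - rotation) %% len)
    feats$end <- as.integer(feats$start + feats$end_width)
    sequence <- paste0(substr(sequence, rotation + 1L, len),
                       substr(sequence, 1L, rotation))
  }
  feats$wrap <- NULL
  feats$end_width <- NULL
  out <- genome_record(id, sequence, feats, is_circular)
  attr(out, "rotation_offset") <- rotation
  out
}

# parse a GenBank location string -> list(start, end, strand, wrap, width)
# start/end returned 0-based half-open; wrap-around joins keep start at the
# 5' segment and report total width via end_width for post-hoc rotation
parse_gb_location <- function(loc, genome_len) {
  strand <- "+"
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc) || grepl("^order\\(", loc)) {
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  rng <- do.call(rbind, lapply(parts, function(p) {
    xs <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    if (length(xs) == 1L) xs <- c(xs, xs)
    xs
  }))
  wrap <- nrow(rng) > 1L && rng[1, 2] == genome_len && rng[nrow(rng), 1] == 1L
  if (wrap) {
    width <- sum(rng[, 2] - rng[, 1] + 1L)
    list(start = rng[1, 1] - 1L, end = rng[1, 1] - 1L + width, strand = strand,
         wrap = TRUE, end_width = width)
  } else {
    list(start = min(rng[, 1]) - 1L, end = max(rng[, 2]), strand = strand,
         wrap = FALSE, end_width = max(rng[, 2]) - (min(rng[, 1]) - 1L))
  }
}

#' Write a genome record as a GenBank flat file
#'
#' The inverse of [read_genbank()]: internal 0-based half-open coordinates are
#' written as 1-based inclusive GenBank locations; `pseudogene` features are
#' written as `CDS` with `/pseudo`; recorded frameshift positions go into a
#' `/note`.
#'
#' @param rec a [genome_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(rec, path) {
  len <- genome_length(rec)
  con <- file(path, "w")
  on.exit(close(con))
  topo <- if (rec$is_circular) "circular" else "linear"
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s BCT 01-JAN-2000",
                     rec$id, len, topo), con)
  writeLines("DEFINITION  .", con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", len), con)
  f <- rec$features
  if (nrow(f)) {
    for (i in seq_len(nrow(f))) {
      key <- switch(f$kind[i], CDS = "CDS", pseudogene = "CDS",
                    tRNA = "tRNA", rRNA = "rRNA", other_RNA = "misc_RNA")
      loc <- sprintf("%d..%d", f$start[i] + 1L, f$end[i])
      if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     %-15s %s", key, loc), con)
      if (nzchar(f$locus_tag[i]))
        writeLines(sprintf('                     /locus_tag="%s"', f$locus_tag[i]), con)
      if (nzchar(f$gene_name[i]))
        writeLines(sprintf('                     /gene="%s"', f$gene_name[i]), con)
      if (f$kind[i] == "pseudogene")
        writeLines("                     /pseudo", con)
      fs <- f$frameshift_positions[[i]]
      if (length(fs))
        writeLines(sprintf('                     /note="frameshift_positions:%s"',
                           paste(fs, collapse = ",")), con)
    }
  }
  writeLines("ORIGIN", con)
  s <- tolower(rec$sequence)
  starts <- seq(1L, len, by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, len))
    tens <- substring(chunk, seq(1, nchar(chunk), 10), pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", st, paste(tens, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Write a genome record as FASTA
#'
#' @param rec a [genome_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(rec, path) {
  x <- Biostrings::DNAStringSet(setNames(rec$sequence, rec$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
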