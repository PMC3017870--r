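# GenBank I/O, genome statistics, IGS extraction, ORF extension

toy_record <- function() {
  feats <- tibble::tibble(
    locus_tag = c("g1", "g2", "g3"),
    gene_name = c("abc", "", "xyz"),
    kind = c("CDS", "tRNA", "CDS"),
    start = c(0L, 17L, 71L),
    end = c(10L, 29L, 101L),
    strand = c("+", "-", "+"))
  genome_record("toy", paste(rep("ACGT", 30), collapse = ""), feats,
                is_circular = FALSE)
}

test_that("hand-written GenBank coordinates convert to 0-based half-open", {
  gb <- c(
    "LOCUS       toy 60 bp    DNA     linear BCT 01-JAN-2000",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "     CDS             10..21",
    '                     /locus_tag="gA"',
    "     tRNA            complement(30..41)",
    '                     /locus_tag="gB"',
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtaacgta", 6), collapse = " ")),
    "//")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path)
  rec <- read_genbank(path)
  expect_equal(nchar(rec$sequence), 60L)
  expect_equal(rec$features$start, c(9L, 29L))
  expect_equal(rec$features$end, c(21L, 41L))
  expect_equal(rec$features$strand, c("+", "-"))
  expect_equal(rec$features$kind, c("CDS", "tRNA"))
})

test_that("GenBank write/read round-trip preserves the annotation", {
  rec <- toy_record()
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(rec, path)
  back <- read_genbank(path)
  expect_equal(back$sequence, rec$sequence)
  expect_equal(back$features$start, rec$features$start)
  expect_equal(back$features$end, rec$features$end)
  expect_equal(back$features$strand, rec$features$strand)
  expect_equal(back$features$kind, rec$features$kind)
  expect_equal(back$features$locus_tag, rec$features$locus_tag)
})

test_that("records with no features and missing sequence behave per contract", {
  rec <- genome_record("empty", "ACGTACGT")
  expect_equal(nrow(rec$features), 0L)
  expect_equal(nchar(rec$sequence), 8L)
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS x", "FEATURES", "//"), path)
  expect_error(read_genbank(path), "ORIGIN")
  expect_error(genome_record("bad", "ACRT"), "outside")
})

test_that("unknown feature keys are skipped with a warning", {
  gb <- c("LOCUS       toy 20 bp DNA linear",
          "FEATURES             Location/Qualifiers",
          "     repeat_region   1..5",
          "     CDS             1..9",
          '                     /locus_tag="gA"',
          "ORIGIN",
          "        1 acgtacgtac gtacgtacgt", "//")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path)
  expect_warning(rec <- read_genbank(path), "repeat_region")
  expect_equal(rec$features$locus_tag, "gA")
})

test_that("genome_stats matches brute-force composition and union coverage", {
  rec0 <- genome_record("mini", "ATGC")
  st0 <- genome_stats(rec0)
  expect_equal(st0$gc_fraction, 0.5)
  expect_equal(st0$pct_coding_incl_rna, 0)
  expect_equal(st0$total_genes, 0L)

  rec <- toy_record()
  st <- genome_stats(rec)
  chars <- strsplit(rec$sequence, "")[[1]]
  expect_equal(st$gc_fraction, mean(chars %in% c("G", "C")))
  expect_equal(st$total_genes, 3)
  expect_equal(st$protein_coding, 2)
  expect_equal(st$trna_count, 1)
  # union coverage: features are disjoint here
  expect_equal(st$pct_coding_incl_rna, (10 + 12 + 30) / 120)
  expect_equal(st$median_igs_length, median(c(7, 42)))

  # overlapping CDS bases are counted once
  ov <- genome_record("ov", strrep("ACGT", 10), tibble::tibble(
    locus_tag = c("a", "b"), gene_name = "", kind = "CDS",
    start = c(0L, 5L), end = c(10L, 20L), strand = "+"), is_circular = FALSE)
  expect_equal(genome_stats(ov)$pct_protein_coding, 20 / 40)
})

test_that("IGS extraction handles abutting, overlapping and wrap-around pairs", {
  mk <- function(starts, ends, circ = FALSE) {
    genome_record("t", strrep("ACGT", 30), tibble::tibble(
      locus_tag = paste0("g", seq_along(starts)), gene_name = "",
      kind = "CDS", start = as.integer(starts), end = as.integer(ends),
      strand = "+"), is_circular = circ)
  }
  # abutting genes give one zero-length record
  ab <- extract_igs(mk(c(0, 10), c(10, 20)))
  expect_equal(nrow(ab), 1L)
  expect_equal(ab$length, 0L)
  # overlapping genes give no record
  expect_equal(nrow(extract_igs(mk(c(0, 5), c(10, 20)))), 0L)
  # linear toy with gaps 7 and 42
  ig <- extract_igs(toy_record())
  expect_equal(ig$length, c(7L, 42L))
  expect_equal(ig$left_locus, c("g1", "g2"))
  # circular genome: wrap-around spacer included and lengths conserve
  circ <- mk(c(10, 50), c(30, 90), circ = TRUE)
  igc <- extract_igs(circ)
  expect_equal(nrow(igc), 2L)
  expect_equal(sum(igc$length) + (30 - 10) + (90 - 50), 120)
})

test_that("IGS length conservation holds on random non-overlapping annotations", {
  set.seed(19)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    bounds <- sort(sample(0:200, 2 * n))
    feats <- tibble::tibble(
      locus_tag = paste0("g", 1:n), gene_name = "", kind = "CDS",
      start = bounds[seq(1, 2 * n, 2)], end = bounds[seq(2, 2 * n, 2)],
      strand = "+")
    feats <- feats[feats$start < feats$end, ]
    if (nrow(feats) < 2) next
    rec <- genome_record("r", random_dna(200), feats, is_circular = TRUE)
    ig <- extract_igs(rec)
    expect_equal(sum(ig$length) + sum(feats$end - feats$start), 200)
  }
})

test_that("extend_orf finds in-frame starts and stops on both strands", {
  # layout: CCC | ATG(3) | AAACCC | ATG GCT GCT GAA (12-23) | TAA(24) | GGG
  seqp <- paste0("CCC", "ATG", "AAACCC", "ATGGCTGCTGAA", "TAA", "GGG")
  rec <- genome_record("orf", seqp, is_circular = FALSE)
  # already bounded by ATG...TAA: unchanged
  r0 <- extend_orf(rec, 12, 27, "+")
  expect_equal(r0$start, 12); expect_equal(r0$end, 27)
  # closest in-frame ATG is 6 bp upstream
  r1 <- extend_orf(rec, 18, 27, "+")
  expect_equal(r1$start, 12)
  expect_true(r1$found_start)
  # downstream in-frame stop is included
  r2 <- extend_orf(rec, 12, 24, "+")
  expect_equal(r2$end, 27)
  # minus-strand mirror of the upstream-ATG case
  rc <- genome_record("orfrc", revcomp(seqp), is_circular = FALSE)
  len <- nchar(seqp)
  r3 <- extend_orf(rc, len - 27, len - 18, "-")
  expect_equal(r3$end, len - 12)
  expect_true(r3$found_start)
})
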