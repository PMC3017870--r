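# Homopolymer tracts, GC profile/skew, origin prediction, dnaA boxes

test_that("find_homopolymers returns maximal qualifying runs", {
  expect_equal(nrow(find_homopolymers(strrep("ACGT", 5), min_len = 9)), 0L)
  tr <- find_homopolymers(paste0("CC", strrep("A", 9), "GG", strrep("T", 12), "C"),
                          min_len = 9)
  expect_equal(tr$base, c("A", "T"))
  expect_equal(tr$start, c(2L, 13L))
  expect_equal(tr$length, c(9L, 12L))
  expect_error(find_homopolymers("AAAA", min_len = 1), "min_len")
})

test_that("find_homopolymers agrees with the regex oracle on random strings", {
  set.seed(71)
  for (i in 1:50) {
    s <- random_dna(3000, c(A = .36, C = .14, G = .14, T = .36))
    got <- as.data.frame(find_homopolymers(s, min_len = 6))
    want <- oracle_homopolymers(s, min_len = 6)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("coding-strand tract counting maps minus-strand polyT to polyA", {
  # plus gene with A9; minus gene whose genomic strand shows T10
  plus_gene <- paste0("ATG", strrep("A", 9), "GGGTAA")            # 18 nt
  minus_gene <- paste0("ATG", strrep("A", 10), "CCGTAA")          # 19 nt
  seqp <- paste0("CC", plus_gene, "CCCC", revcomp(minus_gene), "GG")
  feats <- tibble::tibble(
    locus_tag = c("p", "m"), gene_name = "", kind = "CDS",
    start = c(2L, 24L), end = c(20L, 43L), strand = c("+", "-"))
  rec <- genome_record("t", seqp, feats, is_circular = FALSE)
  tr <- cds_homopolymer_tracts(rec, min_len = 9, strand = "coding")
  expect_equal(nrow(tr), 2L)
  expect_equal(tr$base, c("A", "A"))
  # genomic coordinates point at the actual runs
  for (i in seq_len(nrow(tr))) {
    run <- substr(rec$sequence, tr$start[i] + 1, tr$start[i] + tr$length[i])
    expect_true(run %in% c(strrep("A", tr$length[i]), strrep("T", tr$length[i])))
  }
  expect_equal(count_long_tracts_in_cds(rec, min_len = 9), 2L)
  # genomic convention sees the A-run and the T-run directly
  trg <- cds_homopolymer_tracts(rec, min_len = 9, strand = "genomic")
  expect_setequal(trg$base, c("A", "T"))
  # empty genome
  expect_equal(count_long_tracts_in_cds(genome_record("e", "ACGT")), 0L)
})

test_that("gc_profile matches per-window recounts and revcomp antisymmetry", {
  expect_equal(gc_profile(strrep("G", 50), window = 50, step = 10,
                          circular = FALSE)$gc_skew, 1)
  expect_equal(gc_profile(strrep("C", 50), window = 50, step = 10,
                          circular = FALSE)$gc_skew, -1)
  expect_equal(gc_profile(strrep("GC", 25), window = 50, step = 10,
                          circular = FALSE)$gc_skew, 0)
  expect_error(gc_profile("ACGT", window = 10), "window")

  set.seed(5)
  s <- random_dna(4000, c(A = .3, C = .15, G = .25, T = .3))
  p <- gc_profile(s, window = 500, step = 100, circular = FALSE)
  # recount a few windows from raw characters
  for (i in c(1, 10, 20)) {
    w <- substr(s, (i - 1) * 100 + 1, (i - 1) * 100 + 500)
    g <- lengths(regmatches(w, gregexpr("G", w)))
    cc <- lengths(regmatches(w, gregexpr("C", w)))
    expect_equal(p$gc_skew[i], (g - cc) / (g + cc))
    expect_equal(p$gc_content[i], (g + cc) / 500)
  }
  # reverse complement: skew profile is the negated, reversed profile
  prc <- gc_profile(revcomp(s), window = 500, step = 100, circular = FALSE)
  expect_equal(prc$gc_skew, rev(-p$gc_skew))
  # windows with G+C = 0 are flagged, not dropped
  p0 <- gc_profile(strrep("AT", 30), window = 20, step = 20, circular = FALSE)
  expect_true(all(p0$undefined))
  expect_true(all(p0$gc_skew == 0))
})

test_that("cumulative skew peaks at a planted composition switch", {
  set.seed(9)
  half <- function(g, c) random_dna(10000, c(A = .35, C = c, G = g, T = .35))
  s <- paste0(half(.2, .1), half(.1, .2))
  p <- gc_profile(s, window = 1000, step = 10, circular = TRUE)
  oc <- predict_origin(p)
  expect_true(oc$confident)
  # terminus (cumulative max) at the G-rich -> C-rich switch near 10 kb
  expect_lt(min(abs(oc$terminus_pos - 10000), abs(oc$terminus_pos - 20000)),
            2000)
  # uniform random sequence: no confident origin
  pu <- gc_profile(random_dna(20000, c(A = .36, C = .14, G = .14, T = .36)),
                   window = 1000, step = 10, circular = TRUE)
  expect_false(predict_origin(pu)$confident)
})

test_that("dnaA box search honors IUPAC codes and both strands", {
  h1 <- find_dnaa_boxes("TTATACACA")
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$strand, "+"); expect_equal(h1$start, 0L)
  h2 <- find_dnaa_boxes(revcomp("TTATACACA"))
  expect_equal(h2$strand, "-"); expect_equal(h2$start, 0L)
  expect_error(find_dnaa_boxes("ACGT", pattern = "TTZT"), "IUPAC")
  # clustering: 4 boxes within 300 bp form one cluster
  hits <- tibble::tibble(start = c(10L, 60L, 150L, 260L, 5000L),
                         strand = "+", matched_text = "TTATACACA")
  cl <- cluster_dnaa_boxes(hits, window = 300, min_count = 4)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_hits, 4L)
  expect_equal(nrow(cluster_dnaa_boxes(hits, window = 300, min_count = 5)), 0L)
})
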