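# Inverted-repeat (palindrome) scanner

# construct a palindrome with non-pairing flanks and gap so that the planted
# arms are exactly maximal (C pairs with G only; flanks/gap are all C)
planted_palindrome <- function(arm_len = 30, gap_len = 5, n_mismatch = 0,
                               seed = 1) {
  set.seed(seed)
  arm <- random_dna(arm_len, c(A = .3, C = .2, G = .2, T = .3))
  arm2 <- revcomp(arm)
  if (n_mismatch > 0) {
    # substitute interior positions (never the ends, which must pair)
    at <- sample(2:(arm_len - 1), n_mismatch)
    ch <- strsplit(arm2, "")[[1]]
    for (i in at) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
    arm2 <- paste(ch, collapse = "")
  }
  list(seq = paste0(strrep("C", 50), arm, strrep("C", gap_len), arm2,
                    strrep("C", 50)),
       arm = arm, start = 50L)
}

test_that("an exact planted palindrome is found with the right geometry", {
  pp <- planted_palindrome(arm_len = 30, gap_len = 5)
  hits <- find_palindromes(pp$seq)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$arm1_start, 50L)
  expect_equal(hits$arm_length, 30L)
  expect_equal(hits$gap, 5L)
  expect_equal(hits$mismatches, 0L)
  expect_equal(hits$span, 65L)
})

test_that("the mismatch budget is enforced", {
  pp <- planted_palindrome(arm_len = 30, gap_len = 5, n_mismatch = 4, seed = 3)
  expect_equal(nrow(find_palindromes(pp$seq, max_mismatch = 3)), 0L)
  h4 <- find_palindromes(pp$seq, max_mismatch = 4)
  expect_equal(nrow(h4), 1L)
  expect_equal(h4$mismatches, 4L)
})

test_that("every reported hit verifies its own constraints", {
  set.seed(11)
  for (i in 1:20) {
    s <- random_dna(1500, c(A = .36, C = .14, G = .14, T = .36))
    hits <- find_palindromes(s, min_arm = 8, max_gap = 10, max_mismatch = 2,
                             suppress = FALSE)
    for (j in seq_len(nrow(hits))) {
      a1 <- substr(s, hits$arm1_start[j] + 1,
                   hits$arm1_start[j] + hits$arm_length[j])
      a2 <- substr(s, hits$arm2_start[j] + 1,
                   hits$arm2_start[j] + hits$arm_length[j])
      mm <- sum(strsplit(a2, "")[[1]] != strsplit(revcomp(a1), "")[[1]])
      expect_lte(mm, 2)
      expect_equal(mm, hits$mismatches[j])
      expect_gte(hits$gap[j], 0); expect_lte(hits$gap[j], 10)
      expect_gte(hits$arm_length[j], 8)
    }
  }
})

test_that("the scanner equals the brute-force oracle on short sequences", {
  set.seed(23)
  for (i in 1:10) {
    s <- random_dna(600, c(A = .36, C = .14, G = .14, T = .36))
    got <- as.data.frame(find_palindromes(s, min_arm = 8, max_gap = 12,
                                          max_mismatch = 2, suppress = FALSE))
    got <- got[order(got$arm1_start, got$arm2_start),
               c("arm1_start", "arm2_start", "arm_length", "gap", "mismatches")]
    want <- oracle_palindromes(s, min_arm = 8, max_arm = 1000, max_gap = 12,
                               max_mismatch = 2)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("overlap suppression keeps the longest arm, then fewest mismatches", {
  hits <- tibble::tibble(
    arm1_start = c(0L, 2L, 100L), arm2_start = c(40L, 44L, 140L),
    arm_length = c(10L, 12L, 10L), gap = c(30L, 30L, 30L),
    mismatches = c(0L, 1L, 0L)) |>
    dplyr::mutate(start = arm1_start, end = arm2_start + arm_length,
                  span = 2L * arm_length + gap)
  kept <- reducta:::suppress_palindromes(hits)
  expect_equal(kept$arm1_start, c(2L, 100L))
})

test_that("hits are classified against the annotation", {
  pp <- planted_palindrome(arm_len = 30, gap_len = 4, seed = 8)
  n <- nchar(pp$seq)
  feats <- tibble::tibble(locus_tag = "g1", gene_name = "", kind = "CDS",
                          start = 0L, end = 40L, strand = "+")
  rec <- genome_record("t", pp$seq, feats, is_circular = FALSE)
  hits <- find_palindromes(rec)
  expect_equal(hits$igs_overlap, "fully_igs")
  feats2 <- tibble::tibble(locus_tag = "g1", gene_name = "", kind = "CDS",
                           start = 0L, end = as.integer(n), strand = "+")
  rec2 <- genome_record("t2", pp$seq, feats2, is_circular = FALSE)
  expect_equal(find_palindromes(rec2)$igs_overlap, "genic")
})
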