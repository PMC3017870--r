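# Protein alignment, reciprocal best hits, ortholog table, screen rules


aa_letters <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
rand_aa <- function(n) paste(sample(aa_letters, n, TRUE), collapse = "")

test_that("align_proteins scores match an independent affine-gap DP", {
  a <- rand_aa(25)
  hit <- align_proteins(a, a)
  expect_equal(hit$subject_coverage, 1.0)
  expect_equal(hit$score, oracle_sw_score(a, a))
  expect_error(align_proteins("", "ACD"), "empty")
  set.seed(31)
  for (i in 1:25) {
    x <- rand_aa(sample(10:30, 1)); y <- rand_aa(sample(10:30, 1))
    expect_equal(align_proteins(x, y)$score, oracle_sw_score(x, y))
  }
})

test_that("unrelated proteins score near background with small coverage", {
  set.seed(37)
  x <- rand_aa(100); y <- rand_aa(100)
  hit <- align_proteins(x, y)
  expect_lt(hit$subject_coverage, 0.8)
  expect_gt(hit$evalue_like, 1e-5)
})

test_that("RBH gives the identity map on identical proteomes and is symmetric", {
  set.seed(41)
  prot <- setNames(vapply(1:12, function(i) rand_aa(60), character(1)),
                   paste0("g", 1:12))
  r <- reciprocal_best_hits(prot, prot)
  expect_equal(nrow(r), 12L)
  expect_equal(r$locus_a, r$locus_b)
  # dropping one gene leaves the rest paired, the missing one unpaired
  r2 <- reciprocal_best_hits(prot, prot[-5], prescreen = FALSE)
  expect_equal(nrow(r2), 11L)
  expect_false("g5" %in% r2$locus_a)
  # symmetry
  b <- setNames(vapply(1:12, function(i) rand_aa(60), character(1)),
                paste0("h", 1:12))
  ab <- reciprocal_best_hits(prot, b, prescreen = FALSE)
  ba <- reciprocal_best_hits(b, prot, prescreen = FALSE)
  expect_equal(ab$locus_a, ba$locus_b[match(ab$locus_b, ba$locus_a)])
})

test_that("ortholog table on identical genomes has all families complete", {
  tri <- small_triad()
  g <- subset_record(tri$sim$genomes[[1]], 25)
  copies <- list(a = g, b = g, c = g)
  copies$a$id <- "a"; copies$b$id <- "b"; copies$c$id <- "c"
  tab <- suppressMessages(build_ortholog_table(copies))
  sizes <- table(tab$family_id[!is.na(tab$locus_tag)])
  expect_true(all(sizes == 3))
  # permuted input order yields identical families
  tab2 <- suppressMessages(build_ortholog_table(copies[c(3, 1, 2)]))
  m1 <- ortholog_matrix(tab)
  m2 <- ortholog_matrix(tab2)
  key1 <- paste(m1$a, m1$b, m1$c)
  key2 <- paste(m2$a, m2$b, m2$c)
  expect_setequal(key1, key2)
})

test_that("families recover the simulator manifest exactly", {
  tri <- small_triad()
  sim <- tri$sim
  tab <- tri$table
  got <- tab |> dplyr::filter(!is.na(locus_tag)) |>
    dplyr::inner_join(sim$manifest$family_maps, by = c("genome", "locus_tag"),
                      suffix = c("", "_true"))
  # each recovered family maps to exactly one true family and vice versa
  grp <- got |> dplyr::distinct(family_id, family_id_true)
  expect_equal(anyDuplicated(grp$family_id), 0L)
  expect_equal(anyDuplicated(grp$family_id_true), 0L)
  # absences agree with the manifest
  truth_n <- sim$manifest$family_maps |> dplyr::count(family_id)
  got_n <- got |> dplyr::count(family_id_true)
  expect_equal(nrow(got_n), nrow(truth_n))
})

test_that("synteny mode requires equal gene counts and hybrid rescues", {
  tri <- small_triad()
  sim <- tri$sim
  counts <- vapply(sim$genomes, function(g) nrow(g$features), integer(1))
  if (length(unique(counts)) > 1) {
    expect_error(build_ortholog_table(sim$genomes, mode = "synteny"), "synteny")
  } else {
    succeed()
  }
})

test_that("presence screen applies coverage/e-value thresholds and exceptions", {
  hits <- tibble::tibble(
    gene = c("x", "y", "ftsY"),
    subject_coverage = c(0.75, 0.59, 0.55),
    evalue_like = c(1e-10, 1e-40, 1e-8))
  out <- classify_hit(hits)
  expect_equal(out$call, c("present", "absent", "present"))
  # high coverage but weak e-value fails
  out2 <- classify_hit(tibble::tibble(subject_coverage = 0.9,
                                      evalue_like = 1e-3))
  expect_equal(out2$call, "absent")
})

test_that("tRNA pseudogene flags are rescued by secondary structure", {
  r <- classify_trna(c(8, 50, 12), c(28, 50, 4))
  expect_equal(r$call, c("functional", "functional", "flagged_pseudo"))
  expect_equal(r$flagged, c(TRUE, FALSE, TRUE))
})
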