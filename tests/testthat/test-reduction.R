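# Gene-state classification, Dollo events, hotspot scan, IGS comparison

TREE3 <- "((vafer:0.05,floridanus:0.05):0.03,pennsylvanicus:0.10);"

# build a 3-genome family fixture from per-genome CDS variants
family_fixture <- function(variants) {
  gids <- names(variants)
  genomes <- lapply(gids, function(g) {
    nt <- variants[[g]]
    if (is.na(nt)) {
      # gene deleted: keep the flanking anchors only
      feats <- tibble::tibble(locus_tag = c("a1", "a2"), gene_name = "",
                              kind = "CDS", start = c(0L, 130L),
                              end = c(60L, 190L), strand = "+")
      seqp <- paste0(anchor1, strrep("C", 70), anchor2)
    } else {
      feats <- tibble::tibble(
        locus_tag = c("a1", "x", "a2"), gene_name = "", kind = "CDS",
        start = c(0L, 70L, as.integer(80 + nchar(nt))),
        end = c(60L, as.integer(70 + nchar(nt)),
                as.integer(140 + nchar(nt))), strand = "+")
      seqp <- paste0(anchor1, strrep("C", 10), nt, strrep("C", 10), anchor2)
    }
    genome_record(g, seqp, feats, is_circular = FALSE)
  })
  names(genomes) <- gids
  tab <- suppressMessages(build_ortholog_table(genomes, mode = "rbh"))
  list(genomes = genomes, table = tab)
}

set.seed(101)
anchor1 <- paste0("ATG", random_codons(18), "TAA")   # 60 nt anchor gene
anchor2 <- paste0("ATG", random_codons(18), "TAA")
base_gene <- paste0("ATG", random_codons(30),
                    strrep("A", 12),   # a 12-A tract, frame preserved
                    random_codons(30), "TAA")

test_that("gene states cover intact, slippage, pseudogene and truncation", {
  # single 1-bp indel inside the 11-A tract, otherwise full length
  tract_at <- 3 + 30 * 3
  slipped <- paste0(substr(base_gene, 1, tract_at), # delete one tract A
                    substr(base_gene, tract_at + 2, nchar(base_gene)))
  # two separate disruptive indels
  two_indel <- paste0(substr(slipped, 1, 20), substr(slipped, 22, nchar(slipped)))
  # nonsense mutation only
  nonsense <- base_gene
  substr(nonsense, 3 + 45 * 3 + 1, 3 + 45 * 3 + 3) <- "TAA"
  # truncated to under 60%
  trunc <- paste0(substr(base_gene, 1, floor(nchar(base_gene) * 0.4) %/% 3 * 3),
                  "TAA")

  fx <- family_fixture(list(vafer = slipped, floridanus = base_gene,
                            pennsylvanicus = base_gene))
  st <- suppressWarnings(assign_gene_states(fx$table, fx$genomes))
  fam <- fx$table$family_id[!is.na(fx$table$locus_tag) &
                              fx$table$locus_tag == "x"][1]
  stx <- st[st$family_id == fam, ]
  expect_equal(stx$state[stx$genome == "vafer"], "FRAMESHIFT_SLIPPAGE")
  expect_equal(stx$indel_sign[stx$genome == "vafer"], -1L)
  expect_gte(stx$tract_len[stx$genome == "vafer"], 7L)
  expect_equal(stx$state[stx$genome == "floridanus"], "INTACT")

  for (bad in list(two_indel, nonsense, trunc)) {
    fx2 <- family_fixture(list(vafer = bad, floridanus = base_gene,
                               pennsylvanicus = base_gene))
    st2 <- suppressWarnings(assign_gene_states(fx2$table, fx2$genomes))
    fam2 <- fx2$table$family_id[!is.na(fx2$table$locus_tag) &
                                  fx2$table$locus_tag == "x"][1]
    expect_equal(st2$state[st2$family_id == fam2 & st2$genome == "vafer"],
                 "PSEUDOGENE")
  }
})

test_that("a missing gene is ABSENT, an unannotated eroded copy PSEUDOGENE", {
  fx <- family_fixture(list(vafer = NA, floridanus = base_gene,
                            pennsylvanicus = base_gene))
  st <- suppressWarnings(assign_gene_states(fx$table, fx$genomes))
  absent_rows <- st[st$genome == "vafer" & is.na(st$locus_tag) &
                      !is.na(st$state), ]
  expect_equal(nrow(absent_rows), 1L)
  expect_equal(absent_rows$state, "ABSENT")
})

test_that("shared same-position frameshifts are recognised", {
  tract_at <- 3 + 30 * 3
  slipped <- paste0(substr(base_gene, 1, tract_at),
                    substr(base_gene, tract_at + 2, nchar(base_gene)))
  fx <- family_fixture(list(vafer = slipped, floridanus = slipped,
                            pennsylvanicus = base_gene))
  st <- suppressWarnings(assign_gene_states(fx$table, fx$genomes))
  fs <- detect_slippage_frameshifts(fx$table, fx$genomes, states = st)
  fam <- fx$table$family_id[!is.na(fx$table$locus_tag) &
                              fx$table$locus_tag == "x"][1]
  fsx <- fs[fs$family_id == fam, ]
  expect_equal(nrow(fsx), 2L)
  expect_true(all(fsx$shared))
  # the event table places one FRAMESHIFT on the shared stem
  ev <- reconstruct_events(st, TREE3, fs)
  evx <- ev[ev$family_id == fam & ev$event == "FRAMESHIFT", ]
  expect_equal(nrow(evx), 1L)
  expect_equal(evx$branch, "floridanus+vafer")
  expect_true(evx$shared)
})

test_that("Dollo reconstruction handles the canonical three-leaf cases", {
  allin <- c(vafer = "INTACT", floridanus = "INTACT", pennsylvanicus = "INTACT")
  r0 <- dollo_reconstruct(allin, TREE3)
  expect_equal(nrow(r0$events), 0L)
  expect_true(r0$ancestral_present)
  # independent losses in two non-sister lineages
  r1 <- dollo_reconstruct(c(vafer = "INTACT", floridanus = "ABSENT",
                            pennsylvanicus = "ABSENT"), TREE3)
  expect_setequal(r1$events$branch, c("floridanus", "pennsylvanicus"))
  expect_true(r1$convergent)
  # erosion + loss on different paths
  r2 <- dollo_reconstruct(c(vafer = "PSEUDOGENE", floridanus = "INTACT",
                            pennsylvanicus = "ABSENT"), TREE3)
  expect_setequal(paste(r2$events$event, r2$events$branch),
                  c("EROSION vafer", "LOSS pennsylvanicus"))
  expect_true(r2$convergent)
  # sister losses collapse to one stem event
  r3 <- dollo_reconstruct(c(vafer = "ABSENT", floridanus = "ABSENT",
                            pennsylvanicus = "INTACT"), TREE3)
  expect_equal(r3$events$branch, "floridanus+vafer")
  expect_false(r3$convergent)
})

test_that("summarize_events counts per branch and per lineage", {
  st <- structure(tibble::tibble(
    family_id = rep(c("f1", "f2", "f3"), each = 3),
    genome = rep(c("vafer", "floridanus", "pennsylvanicus"), 3),
    locus_tag = "x",
    state = c("ABSENT", "ABSENT", "INTACT",     # stem loss
              "INTACT", "INTACT", "INTACT",     # nothing
              "PSEUDOGENE", "INTACT", "INTACT"),# vafer erosion
    indel_pos = NA_integer_, indel_sign = NA_integer_,
    tract_base = NA_character_, tract_len = NA_integer_,
    ref_pos = NA_integer_),
    genomes = c("vafer", "floridanus", "pennsylvanicus"))
  ev <- reconstruct_events(st, TREE3)
  sm <- summarize_events(ev, st)
  lc <- sm$lineage_counts
  expect_equal(lc$missing_or_eroded[lc$lineage == "vafer"], 2L)
  expect_equal(lc$missing_or_eroded[lc$lineage == "floridanus"], 1L)
  expect_equal(lc$missing_or_eroded[lc$lineage == "pennsylvanicus"], 0L)
  expect_equal(sm$n_ancestral, 3L)
  expect_equal(sm$n_all_intact, 1L)
})

test_that("hotspot scan flags planted clusters and not uniform spacings", {
  # evenly spaced positions: nothing significant
  even <- seq(0, 699999, by = 70000)
  h0 <- hotspot_scan(even, 700000, window = 32000, n_perm = 999, seed = 5)
  expect_equal(nrow(h0), 0L)
  expect_gte(attr(h0, "best")$p_perm, 0.05)
  # 8 of 31 positions inside one 30-kb window
  set.seed(6)
  pos <- c(runif(23, 0, 700000), runif(8, 100000, 130000))
  h1 <- hotspot_scan(pos, 700000, window = 30000, n_perm = 999, seed = 5,
                     origin_pos = 115000)
  expect_gte(nrow(h1), 1L)
  expect_lt(min(h1$p_perm), 0.01)
  expect_true(any(h1$near_origin))
  # empty input
  expect_equal(nrow(hotspot_scan(numeric(0), 1e6, n_perm = 999)), 0L)
  expect_error(hotspot_scan(c(1, 2), 1e6, n_perm = 99), "n_perm")
})

test_that("hotspot p-values are valid under the uniform null", {
  set.seed(8)
  reps <- 60
  pvals <- vapply(seq_len(reps), function(i) {
    pos <- runif(15, 0, 5e5)
    attr(hotspot_scan(pos, 5e5, window = 32000, n_perm = 999,
                      seed = 1000 + i), "best")$p_perm
  }, numeric(1))
  # stochastically >= uniform: rejection rate at 5% must not exceed ~5%
  expect_lte(mean(pvals < 0.05), 0.08)
})

test_that("IGS classes separate on a triad with planted losses", {
  tri <- small_triad()
  sim <- tri$sim
  cmp <- igs_classify_and_compare(sim$genomes, tri$table, tri$states)
  med <- tidyr::pivot_wider(cmp$class_medians, id_cols = "genome",
                            names_from = "class",
                            values_from = "median_length")
  if ("spanning" %in% names(med)) {
    expect_true(all(med$spanning >= med$conserved, na.rm = TRUE))
  }
  wtest <- cmp$tests[cmp$tests$comparison == "spanning_vs_conserved", ]
  expect_gte(nrow(wtest), 1L)
  expect_lt(min(wtest$p_two_sided), 0.01)
})

test_that("identical genomes yield no spanning IGS and no comparisons", {
  tri <- small_triad()
  g <- subset_record(tri$sim$genomes[[1]], 25)
  copies <- list(a = g, b = g, c = g)
  copies$a$id <- "a"; copies$b$id <- "b"; copies$c$id <- "c"
  tab <- suppressMessages(build_ortholog_table(copies))
  st <- suppressWarnings(assign_gene_states(tab, copies, igs_check = FALSE))
  cmp <- igs_classify_and_compare(copies, tab, st)
  expect_false(any(cmp$igs$spans_missing))
  expect_equal(nrow(cmp$tests), 0L)
})
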