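# Synthetic genome triads and the truth manifest

test_that("simulated ancestor matches the configured composition", {
  cfg <- sim_config(seed = 77, n_genes = 100, p_loss = 0, p_pseudo = 0,
                    p_slip = 0, hotspot_losses = 0)
  anc <- simulate_ancestor(cfg)
  st <- genome_stats(anc$record)
  expect_equal(st$protein_coding, 100L)
  expect_lt(abs(st$gc_fraction - 0.275), 0.01)
  expect_true(anc$record$is_circular)
  # planted palindromes are recoverable at their recorded coordinates
  for (i in seq_len(nrow(anc$palindromes))) {
    p <- anc$palindromes[i, ]
    s <- substr(anc$record$sequence, p$start + 1, p$start + p$span)
    arm1 <- substr(s, 1, p$arm_length)
    arm2 <- substr(s, p$arm_length + p$gap + 1, nchar(s))
    expect_equal(arm2, revcomp(arm1))
  }
})

test_that("zero skew amplitude yields no confident origin call", {
  cfg <- sim_config(seed = 78, n_genes = 100, skew_amplitude = 0,
                    p_loss = 0, p_pseudo = 0, p_slip = 0, hotspot_losses = 0,
                    n_palindromes = 0)
  anc <- simulate_ancestor(cfg)
  oc <- predict_origin(gc_profile(anc$record), anc$record)
  expect_false(oc$confident)
})

test_that("fixtures are byte-identical across runs with the same seed", {
  cfg <- sim_config(seed = 79, n_genes = 30)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture(simulate_triad(cfg), d1)
  write_fixture(simulate_triad(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # and the fixture round-trips through the GenBank reader
  sim <- simulate_triad(cfg)
  gb <- read_genbank(file.path(d1, paste0(names(sim$genomes)[1], ".gb")))
  expect_equal(gb$sequence, sim$genomes[[1]]$sequence)
  expect_equal(gb$features$start, sim$genomes[[1]]$features$start)
  expect_equal(gb$features$kind, sim$genomes[[1]]$features$kind)
})

test_that("zero rates and zero branch lengths reproduce the ancestor", {
  cfg <- sim_config(seed = 80, n_genes = 40, tree = "((a:0,b:0):0,c:0);",
                    p_loss = 0, p_pseudo = 0, p_slip = 0, hotspot_losses = 0)
  sim <- simulate_triad(cfg)
  expect_equal(nrow(sim$manifest$events), 0L)
  for (g in sim$genomes) expect_equal(g$sequence, sim$ancestor$sequence)
  expect_equal(sum(sim$manifest$substitutions$n_sub), 0L)
})

test_that("realized substitutions track the per-site probability", {
  cfg <- sim_config(seed = 81, n_genes = 60,
                    tree = "((a:0.08,b:0.02):0.04,c:0.1);",
                    p_loss = 0, p_pseudo = 0, p_slip = 0, hotspot_losses = 0,
                    n_palindromes = 0)
  sim <- simulate_triad(cfg)
  subs <- sim$manifest$substitutions
  for (i in seq_len(nrow(subs))) {
    expected <- subs$n_expected[i]
    sdev <- sqrt(expected)
    expect_lt(abs(subs$n_sub[i] - expected), 4 * sdev + 0.01 * expected)
    # expected count per site tracks the branch length closely
    t_branch <- expected / subs$n_sites[i]
    expect_gt(t_branch, 0)
  }
})

test_that("manifest events are mutually exclusive and detectable", {
  tri <- small_triad()
  ev <- tri$sim$manifest$events
  # one event per (family, branch)
  expect_equal(anyDuplicated(ev[, c("branch", "family_id")]), 0L)
  # every planted slippage tract is at least the configured length
  fs <- ev[ev$event == "FRAMESHIFT", ]
  if (nrow(fs)) {
    tr <- as.integer(sub(".*tract=(\\d+)", "\\1", fs$detail))
    expect_true(all(tr >= tri$cfg$slip_min_tract))
  }
})

test_that("planted losses and frameshifts are recovered from the genomes", {
  tri <- small_triad()
  sim <- tri$sim
  tab <- tri$table
  st <- tri$states
  map <- tab |> dplyr::filter(!is.na(locus_tag)) |>
    dplyr::inner_join(sim$manifest$family_maps, by = c("genome", "locus_tag"),
                      suffix = c("", "_true")) |>
    dplyr::distinct(family_id, family_id_true)
  ev <- reconstruct_events(st, tri$cfg$tree) |>
    dplyr::inner_join(map, by = "family_id")
  got <- sort(paste(ev$branch, ev$family_id_true, ev$event))
  want <- sort(paste(sim$manifest$events$branch,
                     sim$manifest$events$family_id,
                     sim$manifest$events$event))
  expect_equal(got, want)
})
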