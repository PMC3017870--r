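#' Deletion hotspot scan
#'
#' Slides a circular window over the positions of missing genes and asks, by
#' permutation, whether any window holds more of them than uniform placement
#' would explain. Candidate windows are anchored at each missing position;
#' the null re-places the same number of positions uniformly on the circle
#' and records the maximum window count, so `p_perm` is corrected for
#' scanning. Overlapping significant windows are merged; a merged window
#' overlapping `origin_pos` within one window length is flagged
#' `near_origin`.
#'
#' @param missing_positions genomic coordinates of missing/eroded genes.
#' @param genome_length genome size in bp.
#' @param window window size in bp (< genome_length).
#' @param n_perm number of permutations (>= 999).
#' @param seed RNG seed for the permutation null.
#' @param origin_pos optional replication origin coordinate.
#' @param alpha significance level for reporting windows.
#' @return tibble: `window_start`, `window_end`, `n_missing_in_window`,
#'   `n_missing_total`, `p_perm`, `near_origin`; merged windows with
#'   `p_perm < alpha` (zero rows when nothing is significant). The best
#'   candidate window is attached as attribute `best`.
#' @export
hotspot_scan <- function(missing_positions, genome_length, window = 32000L,
                         n_perm = 9999L, seed = NULL, origin_pos = NULL,
                         alpha = 0.05) {
  stopifnot(n_perm >= 999L, window < genome_length)
  empty <- tibble(window_start = integer(), window_end = integer(),
                  n_missing_in_window = integer(), n_missing_total = integer(),
                  p_perm = numeric(), near_origin = logical())
  pos <- sort(missing_positions %% genome_length)
  n <- length(pos)
  if (!n) return(empty)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  count_anchored <- function(p) {
    # windows [p_i, p_i + window) on the circle
    vapply(p, function(a) sum(((p - a) %% genome_length) < window), integer(1))
  }
  obs <- count_anchored(pos)
  null_max <- vapply(seq_len(n_perm), function(i) {
    max(count_anchored(sort(runif(n, 0, genome_length))))
  }, integer(1))
  p_of <- vapply(obs, function(k) (1 + sum(null_max >= k)) / (1 + n_perm),
                 numeric(1))
  cand <- tibble(window_start = as.integer(pos),
                 window_end = as.integer((pos + window)),
                 n_missing_in_window = obs, n_missing_total = n,
                 p_perm = p_of)
  best <- cand[which.max(cand$n_missing_in_window), ]
  sig <- cand[cand$p_perm < alpha, ]
  out <- if (nrow(sig)) {
    ir <- IRanges::reduce(IRanges::IRanges(sig$window_start + 1L,
                                           sig$window_end))
    bind_rows(lapply(seq_along(ir), function(i) {
      s <- IRanges::start(ir)[i] - 1L; e <- IRanges::end(ir)[i]
      inwin <- sig$window_start >= s & sig$window_end <= e
      tibble(window_start = s, window_end = e,
             n_missing_in_window = max(sig$n_missing_in_window[inwin]),
             n_missing_total = n,
             p_perm = min(sig$p_perm[inwin]))
    }))
  } else empty[, setdiff(names(empty), "near_origin")]
  near <- function(s, e) {
    if (is.null(origin_pos)) return(NA)
    o <- origin_pos %% genome_length
    inside <- ((o - s) %% genome_length) <= (e - s)
    d <- min(circular_dist(o, s, genome_length),
             circular_dist(o, e %% genome_length, genome_length))
    inside || d <= window
  }
  out$near_origin <- if (nrow(out)) {
    mapply(near, out$window_start, out$window_end)
  } else logical(0)
  best$near_origin <- near(best$window_start, best$window_end)
  attr(out, "best") <- best
  out
}

#' Classify IGS records and compare length classes
#'
#' Labels each intergenic spacer of each genome as spanning missing genes
#' (at least one family located between its flanking loci in the conserved
#' gene order is absent or eroded in this genome but present in another) or
#' conserved, then compares the two length classes within each genome and
#' the spanning classes across genomes with two-sided rank-sum tests.
#'
#' @param genomes named list of [genome_record()]s.
#' @param table an `ortholog_table`.
#' @param states a `gene_states` tibble from [assign_gene_states()].
#' @return list: `igs` (long tibble with `genome`, flanks, `length`,
#'   `spans_missing`), `class_medians`, `tests`.
#' @export
igs_classify_and_compare <- function(genomes, table, states) {
  gids <- attr(table, "genomes") %||% unique(table$genome)
  state_wide <- tidyr::pivot_wider(states, id_cols = "family_id",
                                   names_from = "genome",
                                   values_from = "state")
  # family of each locus per genome, and each genome's family-by-position
  lookup <- setNames(table$family_id,
                     paste0(table$genome, "::", table$locus_tag))
  by_pos <- lapply(gids, function(h) {
    sub <- table[table$genome == h & !is.na(table$locus_tag), ]
    sub <- sub[order(sub$pos_index), ]
    list(fams = sub$family_id,
         rank = setNames(seq_len(nrow(sub)), sub$family_id))
  })
  names(by_pos) <- gids
  missing_flags <- lapply(gids, function(g) {
    own <- state_wide[[g]]
    others <- state_wide[, setdiff(gids, g), drop = FALSE]
    present_elsewhere <- apply(as.matrix(others), 1, function(r)
      any(r %in% c("INTACT", "FRAMESHIFT_SLIPPAGE"), na.rm = TRUE))
    miss <- !is.na(own) & own %in% c("ABSENT", "PSEUDOGENE") & present_elsewhere
    setNames(miss, state_wide$family_id)
  })
  names(missing_flags) <- gids
  # the families an IGS of genome g spans are those whose members, in any
  # other genome, lie in gene order strictly between the orthologs of the
  # two flanking loci (exact under conserved gene order)
  igs_all <- bind_rows(lapply(gids, function(g) {
    ig <- extract_igs(genomes[[g]])
    if (!nrow(ig)) return(NULL)
    spans <- vapply(seq_len(nrow(ig)), function(i) {
      fl <- lookup[paste0(g, "::", ig$left_locus[i])]
      fr <- lookup[paste0(g, "::", ig$right_locus[i])]
      if (is.na(fl) || is.na(fr)) return(FALSE)
      for (h in setdiff(gids, g)) {
        bp <- by_pos[[h]]
        pl <- bp$rank[fl]; pr <- bp$rank[fr]
        if (is.na(pl) || is.na(pr)) next
        nh <- length(bp$fams)
        between <- if (pr > pl + 1) bp$fams[(pl + 1):(pr - 1)]
                   else if (pr <= pl) bp$fams[c(seq_len(max(0, pr - 1)),
                                                if (pl < nh) (pl + 1):nh)]
                   else character(0)
        if (any(missing_flags[[g]][between], na.rm = TRUE)) return(TRUE)
      }
      FALSE
    }, logical(1))
    mutate(ig, genome = g, spans_missing = spans)
  }))
  class_medians <- igs_all |>
    mutate(class = ifelse(.data$spans_missing, "spanning", "conserved")) |>
    group_by(.data$genome, .data$class) |>
    summarise(n = n(), median_length = median(.data$length), .groups = "drop")
  tests <- list()
  for (g in gids) {
    x <- igs_all$length[igs_all$genome == g & igs_all$spans_missing]
    y <- igs_all$length[igs_all$genome == g & !igs_all$spans_missing]
    if (length(x) >= 1 && length(y) >= 1) {
      r <- rank_sum_test(x, y)
      tests[[length(tests) + 1L]] <-
        tibble(comparison = "spanning_vs_conserved", genome_a = g,
               genome_b = g, statistic = r$statistic,
               p_two_sided = r$p_two_sided, method = r$method)
    }
  }
  for (p in utils::combn(gids, 2, simplify = FALSE)) {
    x <- igs_all$length[igs_all$genome == p[1] & igs_all$spans_missing]
    y <- igs_all$length[igs_all$genome == p[2] & igs_all$spans_missing]
    if (length(x) >= 1 && length(y) >= 1) {
      r <- rank_sum_test(x, y)
      tests[[length(tests) + 1L]] <-
        tibble(comparison = "spanning_vs_spanning", genome_a = p[1],
               genome_b = p[2], statistic = r$statistic,
               p_two_sided = r$p_two_sided, method = r$method)
    }
  }
  list(igs = igs_all, class_medians = class_medians, tests = bind_rows(tests))
}
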