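#' Run the full genome-reduction analysis on a genome set
#'
#' End-to-end comparative pipeline: ortholog table (RBH + synteny), gene-state
#' classification, slippage-frameshift detection, Dollo event reconstruction
#' and per-lineage summaries, replication-origin prediction from GC skew,
#' deletion-hotspot scan in the focal genome, IGS length-class comparison,
#' and per-gene nonsynonymous rate fold-increases against the outgroup.
#'
#' @param genomes named list of [genome_record()]s (three for the rate
#'   analysis).
#' @param tree rooted newick string or `phylo`; tip labels must match
#'   `names(genomes)`.
#' @param focal genome id used for the hotspot scan and origin call
#'   (default: first tip).
#' @param min_tract minimum homopolymer tract length for the slippage rule.
#' @param hotspot_window window size for the deletion hotspot scan (bp).
#' @param n_perm permutations for the hotspot null.
#' @param seed seed for the hotspot permutations.
#' @param mode ortholog table mode, see [build_ortholog_table()].
#' @param igs_check screen intergenic regions of missing genes?
#' @return object of class `reduction_analysis`: list with `table`, `states`,
#'   `frameshifts`, `events`, `summary`, `stats`, `origin`, `hotspot`,
#'   `igs`, `rates`, `fold`, `tree`, `focal`.
#' @export
analyze_reduction <- function(genomes, tree, focal = NULL, min_tract = 7L,
                              hotspot_window = 32000L, n_perm = 9999L,
                              seed = 1L, mode = "hybrid", igs_check = TRUE) {
  ti <- tree_info(tree)
  stopifnot(setequal(names(genomes), ti$tree$tip.label))
  focal <- focal %||% ti$tree$tip.label[1]
  table <- build_ortholog_table(genomes, mode = mode)
  states <- assign_gene_states(table, genomes, min_tract = min_tract,
                               igs_check = igs_check)
  frameshifts <- detect_slippage_frameshifts(table, genomes,
                                             min_tract = min_tract,
                                             states = states)
  events <- reconstruct_events(states, ti$tree, frameshifts)
  summary <- summarize_events(events, states)
  stats <- bind_rows(lapply(genomes, genome_stats))

  prof <- gc_profile(genomes[[focal]])
  origin <- predict_origin(prof, genomes[[focal]])

  missing <- missing_gene_positions(table, genomes, states, focal)
  hotspot <- hotspot_scan(missing$position, genome_length(genomes[[focal]]),
                          window = hotspot_window, n_perm = n_perm,
                          seed = seed, origin_pos = origin$origin_pos)

  igs <- igs_classify_and_compare(genomes, table, states)

  rates <- fold <- NULL
  if (length(genomes) == 3) {
    og <- outgroup_of(ti)
    ingroup <- setdiff(ti$tree$tip.label, og)
    l1 <- if (focal %in% ingroup) focal else ingroup[1]
    l2 <- setdiff(ingroup, l1)
    rates <- rate_triples(table, genomes, l1, l2, og,
                          frameshift_calls = frameshifts)
    if (nrow(rates) && any(rates$defined)) fold <- fold_summary(rates)
  }

  structure(list(table = table, states = states, frameshifts = frameshifts,
                 events = events, summary = summary, stats = stats,
                 skew_profile = prof, origin = origin, hotspot = hotspot,
                 missing_positions = missing, igs = igs, rates = rates,
                 fold = fold, tree = ti$tree, focal = focal),
            class = "reduction_analysis")
}

# outgroup of a rooted 3-leaf tree: the tip attached directly to the root
outgroup_of <- function(ti) {
  stopifnot(ti$ntip == 3)
  kids <- ti$tree$edge[ti$tree$edge[, 1] == ti$root, 2]
  tipkid <- kids[kids <= ti$ntip]
  if (length(tipkid) != 1) stop("tree is not a rooted 3-leaf triplet")
  ti$tree$tip.label[tipkid]
}

# genomic positions, in genome g, of genes missing or eroded there but
# present in another genome: pseudogene loci use their own midpoint, absent
# families the midpoint of the gap between the nearest flanking loci
missing_gene_positions <- function(table, genomes, states, g) {
  gids <- attr(table, "genomes") %||% unique(table$genome)
  len <- genome_length(genomes[[g]])
  wide <- tidyr::pivot_wider(states, id_cols = "family_id",
                             names_from = "genome", values_from = "state")
  others <- setdiff(gids, g)
  elsewhere <- apply(as.matrix(wide[, others, drop = FALSE]), 1, function(r)
    any(r %in% c("INTACT", "FRAMESHIFT_SLIPPAGE"), na.rm = TRUE))
  target <- !is.na(wide[[g]]) & wide[[g]] %in% c("ABSENT", "PSEUDOGENE") &
    elsewhere
  fams <- wide$family_id[target]
  if (!length(fams)) {
    return(tibble(family_id = character(), position = numeric(),
                  state = character()))
  }
  f <- genomes[[g]]$features
  sub <- table[table$genome == g, ]
  rows <- lapply(fams, function(fam) {
    st <- wide[[g]][wide$family_id == fam]
    locus <- sub$locus_tag[sub$family_id == fam]
    if (length(locus) == 1 && !is.na(locus)) {
      i <- match(locus, f$locus_tag)
      pos <- (f$start[i] + f$end[i]) / 2
    } else {
      pos <- missing_family_midpoint(table, genomes, g, fam)
      if (is.null(pos)) return(NULL)
    }
    tibble(family_id = fam, position = pos %% len, state = st)
  })
  bind_rows(rows[!vapply(rows, is.null, logical(1))])
}

missing_family_midpoint <- function(table, genomes, g, fam) {
  sub <- table[table$genome == g, ]
  sub <- sub[order(sub$family_id), ]
  i <- match(fam, sub$family_id)
  if (is.na(i)) return(NULL)
  n <- nrow(sub)
  left <- right <- NA_integer_
  for (k in seq_len(n - 1)) {
    j <- ((i - 1 - k) %% n) + 1
    if (!is.na(sub$locus_tag[j])) { left <- j; break }
  }
  for (k in seq_len(n - 1)) {
    j <- ((i - 1 + k) %% n) + 1
    if (!is.na(sub$locus_tag[j])) { right <- j; break }
  }
  if (is.na(left) || is.na(right)) return(NULL)
  rec <- genomes[[g]]
  f <- rec$features
  le <- f$end[match(sub$locus_tag[left], f$locus_tag)]
  rs <- f$start[match(sub$locus_tag[right], f$locus_tag)]
  len <- genome_length(rec)
  if (is.na(le) || is.na(rs)) return(NULL)
  if (rs >= le) (le + rs) / 2 else ((le + rs + len) / 2) %% len
}

#' @export
print.reduction_analysis <- function(x, ...) {
  cat("<reduction_analysis> ", length(unique(x$states$genome)), " genomes, ",
      dplyr::n_distinct(x$table$family_id), " families\n", sep = "")
  cat("  ancestral genes:", x$summary$n_ancestral,
      "| intact in all:", x$summary$n_all_intact, "\n")
  lc <- x$summary$lineage_counts
  for (i in seq_len(nrow(lc))) {
    cat(sprintf("  %s: %d missing/eroded, %d frameshifted\n", lc$lineage[i],
                lc$missing_or_eroded[i], lc$frameshifted[i]))
  }
  cat("  convergent families:",
      paste(x$summary$convergent_families, collapse = ", "), "\n")
  if (!is.null(x$fold)) {
    cat(sprintf("  rate fold-increase: median %.2f (range %.2f-%.2f, n=%d)\n",
                x$fold$median_fold, x$fold$min_fold, x$fold$max_fold,
                x$fold$n_defined))
  }
  co <- x$origin
  cat(sprintf("  origin (%s): %d between %s and %s%s\n", x$focal,
              round(co$origin_pos), co$flank_left, co$flank_right,
              if (co$confident) "" else " (not confident)"))
  invisible(x)
}

#' @export
#' @method tidy reduction_analysis
tidy.reduction_analysis <- function(x, ...) x$summary$lineage_counts

#' @export
#' @method glance reduction_analysis
glance.reduction_analysis <- function(x, ...) {
  tibble(n_families = dplyr::n_distinct(x$table$family_id),
         n_ancestral = x$summary$n_ancestral,
         n_all_intact = x$summary$n_all_intact,
         n_convergent = length(x$summary$convergent_families),
         median_fold = if (!is.null(x$fold)) x$fold$median_fold else NA_real_,
         origin_pos = x$origin$origin_pos,
         origin_confident = x$origin$confident)
}
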