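# Dollo polarization of gene loss and erosion on a rooted tree. Gains are
# forbidden; a gene present (non-ABSENT) in any leaf was present in the root.
# Severity may only increase root-to-leaf (INTACT -> PSEUDOGENE -> ABSENT);
# slippage frameshifts count as intact and are carried as branch annotations.

# parse/validate the input tree; returns an ape "phylo", rooted
as_rooted_tree <- function(tree) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  tree
}

# per-node descendant tip sets and readable branch labels ("a+b" for clades)
tree_info <- function(tree) {
  tree <- as_rooted_tree(tree)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  desc <- vector("list", nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(po))) {
    p <- po[k, 1]; ch <- po[k, 2]
    desc[[p]] <- sort(unique(c(desc[[p]], desc[[ch]])))
  }
  labels <- vapply(seq_len(nnode), function(i) paste(desc[[i]], collapse = "+"),
                   character(1))
  list(tree = tree, ntip = ntip, root = ntip + 1L, postorder = po,
       desc = desc, labels = labels)
}

#' Dollo reconstruction of one gene family's history
#'
#' Places loss and erosion events for one family on a rooted tree under
#' Dollo parsimony: no gains, severity non-decreasing along every
#' root-to-leaf path, minimal number of events, ties resolved toward the
#' leaves (each internal node takes the minimum severity of its children).
#' The family is ancestrally present iff any leaf is non-absent. Slippage
#' frameshift states count as intact here.
#'
#' @param states named character vector leaf -> state (one of
#'   `r paste(GENE_STATES, collapse = ", ")`).
#' @param tree rooted tree (`phylo` or newick string) whose tip labels match
#'   `names(states)`.
#' @return list: `ancestral_present`, `ancestral_intact`, `events` (tibble
#'   `branch`, `event`), `convergent`.
#' @export
dollo_reconstruct <- function(states, tree) {
  ti <- tree_info(tree)
  tips <- ti$tree$tip.label
  stopifnot(setequal(names(states), tips), all(states %in% GENE_STATES))
  nnode <- ti$tree$Nnode
  if (nnode > 10) stop("Dollo search supports at most 10 internal nodes")
  sev <- integer(ti$ntip + nnode)
  sev[seq_len(ti$ntip)] <- state_severity(states[tips])
  if (all(sev[seq_len(ti$ntip)] == 2L)) {
    return(list(ancestral_present = FALSE, ancestral_intact = FALSE,
                events = tibble(branch = character(), event = character()),
                convergent = FALSE))
  }
  # exhaustive search over internal-node severities: severity may only
  # increase along each edge; minimize the event count, then the internal
  # severity sum (events placed as late / leafward as possible)
  grid <- as.matrix(expand.grid(rep(list(0:2), nnode)))
  edges <- ti$tree$edge
  best <- NULL; best_key <- c(Inf, Inf)
  for (r in seq_len(nrow(grid))) {
    sv <- sev
    sv[ti$ntip + seq_len(nnode)] <- grid[r, ]
    d <- sv[edges[, 2]] - sv[edges[, 1]]
    if (any(d < 0)) next
    key <- c(sum(d > 0), sum(grid[r, ]))
    if (key[1] < best_key[1] ||
        (key[1] == best_key[1] && key[2] < best_key[2])) {
      best <- sv; best_key <- key
    }
  }
  sev <- best
  ev <- list()
  for (k in seq_len(nrow(edges))) {
    p <- edges[k, 1]; ch <- edges[k, 2]
    if (sev[ch] > sev[p]) {
      ev[[length(ev) + 1L]] <- tibble(
        branch = ti$labels[ch],
        event = if (sev[ch] == 2L) "LOSS" else "EROSION",
        node = ch)
    }
  }
  events <- if (length(ev)) bind_rows(ev) else
    tibble(branch = character(), event = character(), node = integer())
  conv <- is_convergent(events$node, ti)
  list(ancestral_present = TRUE, ancestral_intact = sev[ti$root] == 0L,
       events = select(events, "branch", "event"), convergent = conv)
}

# events are convergent iff their edges do not all lie on one root-to-leaf
# path, i.e. no single leaf descends from every event edge
is_convergent <- function(nodes, ti) {
  if (length(nodes) < 2) return(FALSE)
  leafsets <- lapply(nodes, function(n) ti$desc[[n]])
  length(Reduce(intersect, leafsets)) == 0
}

#' Build the per-family event table for a genome set
#'
#' Runs [dollo_reconstruct()] on every family of a gene-state table and
#' appends slippage frameshift annotations: frameshifts shared at the same
#' reference position by all tips of a clade are placed once on that clade's
#' stem (`shared = TRUE`), others on the leaf branch where observed.
#'
#' @param states a `gene_states` tibble from [assign_gene_states()].
#' @param tree rooted tree; tips named like the genomes.
#' @param frameshifts optional tibble from [detect_slippage_frameshifts()].
#' @return tibble of class `event_table`: `family_id`, `branch`, `event`
#'   (`LOSS`/`EROSION`/`FRAMESHIFT`), `shared`, `convergent`,
#'   `ancestral_present`.
#' @export
reconstruct_events <- function(states, tree, frameshifts = NULL) {
  ti <- tree_info(tree)
  gids <- attr(states, "genomes") %||% unique(states$genome)
  stopifnot(setequal(gids, ti$tree$tip.label))
  node_of_label <- setNames(seq_along(ti$labels), ti$labels)
  rows <- states |>
    filter(!is.na(.data$state)) |>
    group_by(.data$family_id) |>
    dplyr::group_map(function(df, key) {
      st <- setNames(df$state, df$genome)
      if (length(st) != length(gids)) return(NULL)
      rec <- dollo_reconstruct(st, ti$tree)
      ev <- rec$events
      ev$shared <- FALSE
      # frameshift annotations
      if (!is.null(frameshifts)) {
        fs <- frameshifts[frameshifts$family_id == key$family_id, ]
      } else {
        fs <- df[df$state == "FRAMESHIFT_SLIPPAGE", ]
        if (nrow(fs)) {
          fs$shared <- nrow(fs) > 1 & vapply(seq_len(nrow(fs)), function(k)
            any(abs(fs$ref_pos[k] - fs$ref_pos[-k]) <= 10 &
                  fs$indel_sign[k] == fs$indel_sign[-k]), logical(1))
        }
      }
      if (nrow(fs)) {
        shared_set <- fs$genome[fs$shared %||% FALSE]
        placed <- FALSE
        if (length(shared_set) >= 2) {
          lab <- paste(sort(shared_set), collapse = "+")
          if (lab %in% ti$labels) {  # shared set is a clade: one stem event
            ev <- bind_rows(ev, tibble(branch = lab, event = "FRAMESHIFT",
                                       shared = TRUE))
            placed <- TRUE
          }
        }
        solo <- if (placed) fs$genome[!fs$genome %in% shared_set] else fs$genome
        for (g in solo) {
          ev <- bind_rows(ev, tibble(branch = g, event = "FRAMESHIFT",
                                     shared = FALSE))
        }
      }
      if (!nrow(ev)) return(NULL)
      ev$convergent <- is_convergent(node_of_label[ev$branch], ti)
      mutate(ev, family_id = key$family_id,
             ancestral_present = rec$ancestral_present)
    }) |>
    bind_rows()
  out <- if (nrow(rows)) {
    select(rows, "family_id", "branch", "event", "shared", "convergent",
           "ancestral_present")
  } else {
    tibble(family_id = character(), branch = character(), event = character(),
           shared = logical(), convergent = logical(),
           ancestral_present = logical())
  }
  structure(out, class = c("event_table", class(out)), tree = ti$tree)
}

#' Summarise loss/erosion/frameshift events per branch and per lineage
#'
#' Per-branch event counts, per-lineage "missing or eroded" gene counts
#' (families with at least one loss or erosion event on the branches from
#' the root to that leaf - stem events count for both descendant lineages),
#' per-lineage slippage-frameshift counts, the ancestral gene content, and
#' the convergently affected families.
#'
#' @param events an `event_table` from [reconstruct_events()].
#' @param states the `gene_states` table (used for the ancestral-content and
#'   shared-intact counts).
#' @param tree rooted tree (defaults to the one stored on `events`).
#' @return list: `branch_counts`, `lineage_counts`, `convergent_families`,
#'   `n_ancestral`, `n_all_intact`.
#' @export
summarize_events <- function(events, states = NULL, tree = NULL) {
  ti <- tree_info(tree %||% attr(events, "tree"))
  node_of_label <- setNames(seq_along(ti$labels), ti$labels)
  branch_counts <- events |>
    filter(.data$event %in% c("LOSS", "EROSION")) |>
    group_by(.data$branch, .data$event) |>
    summarise(n = n(), .groups = "drop")
  # path from root to each leaf = branches whose descendant set contains it
  lineage_counts <- bind_rows(lapply(ti$tree$tip.label, function(leaf) {
    onpath <- vapply(events$branch, function(b)
      leaf %in% ti$desc[[node_of_label[[b]]]], logical(1))
    le <- events[onpath & events$event %in% c("LOSS", "EROSION"), ]
    fs <- events[onpath & events$event == "FRAMESHIFT", ]
    tibble(lineage = leaf,
           missing_or_eroded = dplyr::n_distinct(le$family_id),
           frameshifted = dplyr::n_distinct(fs$family_id))
  }))
  conv <- unique(events$family_id[events$convergent])
  n_anc <- n_intact <- NA_integer_
  if (!is.null(states)) {
    per_fam <- states |> filter(!is.na(.data$state)) |>
      group_by(.data$family_id) |>
      summarise(present = any(.data$state != "ABSENT"),
                all_intact = all(.data$state %in%
                                   c("INTACT", "FRAMESHIFT_SLIPPAGE")),
                .groups = "drop")
    n_anc <- sum(per_fam$present)
    n_intact <- sum(per_fam$all_intact)
  }
  list(branch_counts = branch_counts, lineage_counts = lineage_counts,
       convergent_families = conv, n_ancestral = n_anc,
       n_all_intact = n_intact)
}
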