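# Karlin-Altschul constants for BLOSUM62 (ungapped); the e-value-like
# statistic is a ranking/filtering device, not a BLAST replica
KA_LAMBDA <- 0.3176
KA_K <- 0.134

#' Extract the proteome of a genome record
#'
#' Translates every CDS (coding strand, standard code; internal stops kept as
#' `*`, terminal stop stripped) and records each locus' positional index in
#' the full gene order.
#'
#' @param rec a [genome_record()].
#' @return tibble `locus_tag`, `pos_index`, `aa`.
#' @export
proteome <- function(rec) {
  f <- rec$features
  pos <- seq_len(nrow(f))
  keep <- f$kind == "CDS"
  aa <- vapply(which(keep), function(i) {
    p <- translate_cds(feature_seq(rec, i))
    sub("\\*$", "", p)
  }, character(1))
  tibble(locus_tag = f$locus_tag[keep], pos_index = pos[keep], aa = aa)
}

#' Align two protein sequences
#'
#' Smith-Waterman local alignment with BLOSUM62 and affine gaps (open 11,
#' extend 1), plus subject coverage and a Karlin-Altschul e-value-like
#' statistic K m n exp(-lambda S) used for ranking and the presence screen.
#'
#' @param a,b amino-acid strings (query, subject).
#' @return one-row tibble: `score`, `subject_coverage`, `evalue_like`.
#' @export
align_proteins <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty protein sequence", call. = FALSE)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
  s <- Biostrings::score(al)
  cov <- Biostrings::nchar(Biostrings::subject(al)) / nchar(b)
  tibble(score = s, subject_coverage = min(1, cov),
         evalue_like = ka_evalue(s, nchar(a), nchar(b)))
}

ka_evalue <- function(score, m, n) KA_K * m * n * exp(-KA_LAMBDA * score)

# local-alignment scores of one query against a set of candidate subjects
score_against <- function(query, subjects) {
  if (!length(subjects)) return(numeric(0))
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(subjects), Biostrings::AAString(query),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
  al
}

# k-mer index: named list kmer -> integer vector of sequence indices
kmer_index <- function(seqs, k = 4L) {
  km <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1), k:n))
  })
  idx <- rep(seq_along(seqs), lengths(km))
  split(idx, unlist(km))
}

# indices of the top_n candidates in the indexed proteome sharing the most
# k-mers with `s`
prescreen_candidates <- function(s, index, k = 4L, top_n = 5L) {
  n <- nchar(s)
  if (n < k) return(integer(0))
  kms <- unique(substring(s, 1:(n - k + 1), k:n))
  hits <- unlist(index[intersect(kms, names(index))], use.names = FALSE)
  if (!length(hits)) return(integer(0))
  tab <- sort(table(hits), decreasing = TRUE)
  as.integer(names(tab))[seq_len(min(top_n, length(tab)))]
}

# directional best hits from proteome a to proteome b (tibbles from
# proteome()); ties broken by closest relative gene-order position, then
# lexical locus order
best_hits <- function(a, b, prescreen = TRUE, top_n = 5L) {
  index <- if (prescreen) kmer_index(b$aa) else NULL
  na <- max(a$pos_index); nb <- max(b$pos_index)
  rows <- lapply(seq_len(nrow(a)), function(i) {
    cand <- if (prescreen) prescreen_candidates(a$aa[i], index, top_n = top_n)
            else seq_len(nrow(b))
    if (!length(cand)) return(NULL)
    sc <- score_against(a$aa[i], b$aa[cand])
    best <- which(sc == max(sc))
    if (length(best) > 1) {
      dpos <- abs(a$pos_index[i] / na - b$pos_index[cand[best]] / nb)
      best <- best[order(dpos, b$locus_tag[cand[best]])][1]
    }
    tibble(query = a$locus_tag[i], subject = b$locus_tag[cand[best]],
           score = max(sc))
  })
  bind_rows(rows[!vapply(rows, is.null, logical(1))])
}

#' Reciprocal best hits between two proteomes
#'
#' A pair (a, b) is reported iff b is a's best-scoring hit and a is b's.
#' Score ties are broken by the closest relative gene-order position, then
#' lexical locus order. A shared 4-mer prescreen limits the all-vs-all cost;
#' disable it for exhaustive search.
#'
#' @param a,b proteomes: tibbles from [proteome()], or named character
#'   vectors of locus -> protein sequence.
#' @param prescreen use the k-mer prescreen?
#' @param top_n candidates retained per query by the prescreen.
#' @return tibble `locus_a`, `locus_b`, `score`.
#' @export
reciprocal_best_hits <- function(a, b, prescreen = TRUE, top_n = 5L) {
  a <- as_proteome(a); b <- as_proteome(b)
  ab <- best_hits(a, b, prescreen, top_n)
  ba <- best_hits(b, a, prescreen, top_n)
  if (!nrow(ab) || !nrow(ba)) {
    return(tibble(locus_a = character(), locus_b = character(),
                  score = numeric()))
  }
  m <- dplyr::inner_join(ab, ba, by = c(query = "subject", subject = "query"))
  tibble(locus_a = m$query, locus_b = m$subject, score = m$score.x) |>
    arrange(.data$locus_a)
}

as_proteome <- function(x) {
  if (is.data.frame(x)) return(x)
  tibble(locus_tag = names(x), pos_index = seq_along(x), aa = unname(x))
}

#' Build a cross-genome ortholog table
#'
#' Gene families are merged across pairwise reciprocal-best-hit graphs by
#' single linkage. In `hybrid` mode (the default, appropriate for genomes
#' with strictly conserved gene order) loci left unmatched by RBH - RNA
#' genes, pseudogenes, badly fragmented CDS - are assigned by conserved
#' gene-order interpolation between anchor families; `synteny` mode pairs
#' features purely by gene order. Unresolved loci become singleton families.
#' An inconsistent RBH triangle splits the family into singletons (with a
#' message).
#'
#' @param genomes named list of [genome_record()]s (>= 2).
#' @param mode `"hybrid"`, `"rbh"` or `"synteny"`.
#' @param prescreen,top_n passed to [reciprocal_best_hits()].
#' @return tibble of class `ortholog_table`: `family_id`, `genome`,
#'   `locus_tag` (NA = absent), `pos_index`, `kind`.
#' @export
build_ortholog_table <- function(genomes, mode = c("hybrid", "rbh", "synteny"),
                                 prescreen = TRUE, top_n = 5L) {
  mode <- match.arg(mode)
  stopifnot(length(genomes) >= 2)
  gids <- names(genomes) %||% vapply(genomes, function(g) g$id, character(1))
  names(genomes) <- gids

  feats <- lapply(gids, function(g) {
    f <- genomes[[g]]$features
    mutate(f, genome = g, pos_index = row_number())
  })
  names(feats) <- gids
  all_feats <- bind_rows(feats)

  if (mode == "synteny") {
    counts <- vapply(feats, nrow, integer(1))
    if (length(unique(counts)) != 1) {
      stop("synteny mode requires equal feature counts; use hybrid",
           call. = FALSE)
    }
    fam <- bind_rows(lapply(feats, function(f) {
      tibble(family_id = sprintf("fam%04d", f$pos_index), genome = f$genome,
             locus_tag = f$locus_tag, pos_index = f$pos_index, kind = f$kind)
    }))
    return(finish_ortholog_table(fam, gids))
  }

  prots <- lapply(genomes, proteome)
  pairs <- utils::combn(gids, 2, simplify = FALSE)
  edges <- bind_rows(lapply(pairs, function(p) {
    r <- reciprocal_best_hits(prots[[p[1]]], prots[[p[2]]], prescreen, top_n)
    tibble(from = paste0(p[1], "::", r$locus_a),
           to = paste0(p[2], "::", r$locus_b))
  }))
  nodes <- paste0(all_feats$genome, "::", all_feats$locus_tag)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  comp <- igraph::components(g)$membership
  memb <- tibble(genome = all_feats$genome, locus_tag = all_feats$locus_tag,
                 pos_index = all_feats$pos_index, kind = all_feats$kind,
                 comp = comp[nodes])
  # split inconsistent components (>1 locus from one genome)
  dup <- memb |> group_by(.data$comp, .data$genome) |>
    summarise(n = n(), .groups = "drop") |> filter(.data$n > 1)
  if (nrow(dup)) {
    message("split ", length(unique(dup$comp)),
            " inconsistent RBH component(s) into singletons")
    bad <- memb$comp %in% dup$comp
    memb$comp[bad] <- max(memb$comp) + seq_len(sum(bad))
  }
  # singletons keep their own component id (every locus is a vertex)

  if (mode == "hybrid") {
    # coding-strand nucleotide sequence of every feature, for homology
    # verification of gene-order assignments; DNA identity is robust to the
    # frameshifts and nonsense changes that break protein-level scores
    nt_map <- new.env(parent = emptyenv())
    for (g in gids) {
      rec <- genomes[[g]]
      for (i in seq_len(nrow(rec$features))) {
        assign(paste0(g, "::", rec$features$locus_tag[i]),
               feature_seq(rec, i), envir = nt_map)
      }
    }
    memb <- interpolate_by_synteny(memb, gids, nt_map)
  }

  # family ids follow the conserved gene order: families are ranked by their
  # mean positional index so that members absent from the first genome still
  # sort where the gene order puts them
  fam_order <- memb |> group_by(.data$comp) |>
    summarise(key = mean(.data$pos_index), .groups = "drop") |>
    arrange(.data$key)
  fam_map <- setNames(sprintf("fam%04d", seq_len(nrow(fam_order))),
                      fam_order$comp)
  fam <- memb |>
    mutate(family_id = fam_map[as.character(.data$comp)]) |>
    select("family_id", "genome", "locus_tag", "pos_index", "kind")
  finish_ortholog_table(fam, gids)
}

# assign leftover loci between anchor families by conserved gene order.
# Anchor families (present in every genome) delimit intervals; within each
# interval the remaining loci of each genome - singletons and members of
# partial families - are zipped in gene order when every genome with
# leftovers has the same number of them. Each zipped row must pass a
# homology check (local protein alignment against the row's best-supported
# member), so complementary losses in one interval are never merged into a
# chimeric family; rows that verify are merged component-wide, which also
# folds RBH-orphaned loci (e.g. badly frameshifted genes) into their
# partial families.
interpolate_by_synteny <- function(memb, gids, nt_map = NULL) {
  sizes <- memb |> group_by(.data$comp) |>
    summarise(n = dplyr::n_distinct(.data$genome), .groups = "drop")
  anchors <- sizes$comp[sizes$n == length(gids)]
  if (length(anchors) < 2) return(memb)
  apos <- memb |> filter(.data$comp %in% anchors) |>
    tidyr::pivot_wider(id_cols = "comp", names_from = "genome",
                       values_from = "pos_index")
  apos <- arrange(apos, .data[[gids[1]]])
  loose <- memb |> filter(!.data$comp %in% anchors)
  if (!nrow(loose)) return(memb)
  comp_size <- table(loose$comp)
  n_anchor <- nrow(apos)
  next_comp <- max(memb$comp)
  for (k in seq_len(n_anchor)) {
    k2 <- if (k == n_anchor) 1L else k + 1L
    # non-anchor loci per genome strictly between anchor k and anchor k+1
    # (the last interval wraps for circular gene orders)
    slots <- lapply(gids, function(g) {
      lo <- apos[[g]][k]; hi <- apos[[g]][k2]
      u <- loose[loose$genome == g, ]
      if (k < n_anchor) u <- u[u$pos_index > lo & u$pos_index < hi, ]
      else u <- u[u$pos_index > lo | u$pos_index < hi, ]
      u[order((u$pos_index - lo) %% (max(memb$pos_index) + 1L)), ]
    })
    counts <- vapply(slots, nrow, integer(1))
    nz <- counts[counts > 0]
    if (length(nz) < 2 || length(unique(nz)) != 1) next
    for (r in seq_len(nz[1])) {
      members <- bind_rows(lapply(slots, function(s)
        if (nrow(s) >= r) s[r, ] else NULL))
      if (!is.null(nt_map) && nrow(members) >= 2) {
        nt <- vapply(seq_len(nrow(members)), function(m)
          get0(paste0(members$genome[m], "::", members$locus_tag[m]),
               envir = nt_map, ifnotfound = NA_character_),
          character(1))
        # reference: the member of the best-supported (largest) component
        support <- as.integer(comp_size[as.character(members$comp)])
        ref <- which.max(support)
        keep <- vapply(seq_len(nrow(members)), function(m) {
          if (m == ref || members$comp[m] == members$comp[ref]) return(TRUE)
          if (is.na(nt[m]) || is.na(nt[ref])) return(FALSE)
          # local DNA identity: orthologs at these divergences align over
          # most of their length; unrelated AT-rich genes reach only short
          # chance segments
          sc <- Biostrings::pairwiseAlignment(
            Biostrings::DNAString(nt[m]), Biostrings::DNAString(nt[ref]),
            type = "local", substitutionMatrix = dna_submat(),
            gapOpening = 5, gapExtension = 2, scoreOnly = TRUE)
          sc >= 0.6 * min(nchar(nt[m]), nchar(nt[ref]))
        }, logical(1))
        members <- members[keep, ]
      }
      if (nrow(members) >= 2 && length(unique(members$comp)) >= 2) {
        next_comp <- next_comp + 1L
        memb$comp[memb$comp %in% members$comp] <- next_comp
      }
    }
  }
  memb
}

finish_ortholog_table <- function(fam, gids) {
  out <- fam |>
    tidyr::complete(family_id = unique(fam$family_id), genome = gids) |>
    arrange(.data$family_id, match(.data$genome, gids))
  structure(out, class = c("ortholog_table", class(out)), genomes = gids)
}

#' Wide presence/absence view of an ortholog table
#'
#' @param table an `ortholog_table` from [build_ortholog_table()].
#' @return tibble with one row per family and one locus column per genome.
#' @export
ortholog_matrix <- function(table) {
  tidyr::pivot_wider(table, id_cols = "family_id", names_from = "genome",
                     values_from = "locus_tag")
}

#' Presence screen for homology hits
#'
#' A hit is `present` iff it covers at least `min_coverage` of the subject
#' protein and its e-value-like statistic is below `max_e`. Per-gene coverage
#' exceptions are honored (e.g. ftsY at 0.50).
#'
#' @param hits tibble with `subject_coverage` and `evalue_like`, optionally a
#'   `gene` column matched against `exceptions`.
#' @param min_coverage default subject coverage threshold.
#' @param max_e e-value threshold.
#' @param exceptions named numeric vector of per-gene coverage thresholds.
#' @return `hits` with a `call` column (`"present"`/`"absent"`).
#' @export
classify_hit <- function(hits, min_coverage = 0.60, max_e = 1e-5,
                         exceptions = c(ftsY = 0.50)) {
  stopifnot(min_coverage > 0, min_coverage <= 1)
  thr <- rep(min_coverage, nrow(hits))
  if ("gene" %in% names(hits) && length(exceptions)) {
    hit_ex <- match(hits$gene, names(exceptions))
    thr[!is.na(hit_ex)] <- exceptions[hit_ex[!is.na(hit_ex)]]
  }
  mutate(hits, call = ifelse(.data$subject_coverage >= thr &
                               .data$evalue_like < max_e,
                             "present", "absent"))
}

#' Re-evaluate tRNA pseudogene flags
#'
#' tRNA scanners flag a tRNA as a potential pseudogene when its primary
#' structure (HMM) score is below 10 bits or its secondary structure score is
#' below 5 bits. In extremely AT-biased genomes the primary score cutoff is
#' miscalibrated, so a flagged tRNA is rescued to functional when its
#' secondary structure score is at least 5 bits: the final call is
#' functional iff `secondary_score >= 5`.
#'
#' @param primary_score,secondary_score numeric vectors (bits).
#' @return tibble `flagged` (scanner flag) and `call`
#'   (`"functional"`/`"flagged_pseudo"`).
#' @export
classify_trna <- function(primary_score, secondary_score) {
  flagged <- primary_score < 10 | secondary_score < 5
  tibble(primary_score = primary_score, secondary_score = secondary_score,
         flagged = flagged,
         call = ifelse(secondary_score >= 5, "functional", "flagged_pseudo"))
}
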