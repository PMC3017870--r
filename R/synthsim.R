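# Synthetic endosymbiont genome triads with a planted-event truth manifest.
# A genome is built as an ordered list of elements (genes and intergenic
# spacers); branch evolution edits elements, and leaf genomes are assembled
# into genome_records at the end. Planted features that the pipeline must
# recover (slippage tracts, pseudogene disruptions, palindromes) are
# protected from subsequent substitutions so every manifest event remains
# detectable.

#' Simulation configuration
#'
#' Defaults emulate the study conditions of a reduced, extremely AT-biased
#' (~27.5% GC) ant-endosymbiont genome triad: ~600 genes of ~1 kb,
#' geometric spacers (mean 134 bp), strict synteny, GC skew switching sign
#' at the origin/terminus, a handful of slippage frameshifts per lineage,
#' background gene loss/erosion, a deletion hotspot of 8 extra losses in a
#' 32 kb window at the origin of the first lineage, and 10 conserved
#' intergenic palindromes.
#'
#' @param seed mandatory integer seed.
#' @param n_genes number of ancestral genes.
#' @param mean_cds_len mean CDS length (bp, incl. start/stop).
#' @param gc_target genomic GC fraction.
#' @param igs_mean geometric mean intergenic spacer length (bp); the default
#'   puts the spacer median near 134 bp.
#' @param tree rooted 3-leaf newick with branch lengths (subs/site).
#' @param p_loss,p_pseudo per-gene probabilities of loss and
#'   pseudogenization, either a scalar applied to every branch or a named
#'   vector keyed by branch label (leaf name or "a+b" for a clade stem;
#'   unlisted branches get 0). The defaults reproduce the strongly
#'   asymmetric per-lineage reduction of the motivating system.
#' @param p_slip probability of a slippage frameshift for genes carrying a
#'   homopolymer tract of at least `slip_min_tract` bp; scalar or named by
#'   branch like `p_loss`.
#' @param slip_min_tract minimum tract length used when planting slips.
#' @param scar_frac maximum residual gene fraction left by a deletion.
#' @param n_palindromes planted intergenic palindromes.
#' @param palindrome_arm,palindrome_gap arm/gap length ranges (bp).
#' @param skew_amplitude GC-skew amplitude ((G-C)/(G+C) contrast between
#'   replichores).
#' @param origin_frac replication origin position as a fraction of genome
#'   length.
#' @param hotspot_losses,hotspot_width,hotspot_branch extra deletions planted
#'   in a window centred on the origin, on the branch to `hotspot_branch`
#'   (default: first tip).
#' @param annotate_pseudo annotate planted pseudogenes as such (`TRUE`) or
#'   leave them as plain CDS for the classifier to find (default)?
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed, n_genes = 600L, mean_cds_len = 1000L,
                       gc_target = 0.275, igs_mean = 193,
                       tree = "((vafer:0.05,floridanus:0.05):0.03,pennsylvanicus:0.10);",
                       p_loss = c(vafer = 0.027, floridanus = 0.035,
                                  pennsylvanicus = 0.004,
                                  "floridanus+vafer" = 0.005),
                       p_pseudo = c(vafer = 0.005, floridanus = 0.005,
                                    pennsylvanicus = 0.003,
                                    "floridanus+vafer" = 0.002),
                       p_slip = c(vafer = 0.06, floridanus = 0.025,
                                  pennsylvanicus = 0.035,
                                  "floridanus+vafer" = 0.01),
                       slip_min_tract = 9L, scar_frac = 0.3,
                       n_palindromes = 10L, palindrome_arm = c(32L, 58L),
                       palindrome_gap = c(0L, 20L), skew_amplitude = 0.08,
                       origin_frac = 0.65, hotspot_losses = 8L,
                       hotspot_width = 32000L, hotspot_branch = NULL,
                       annotate_pseudo = FALSE) {
  stopifnot(!missing(seed), is.numeric(seed), gc_target > 0, gc_target < 1,
            all(unlist(c(p_loss, p_pseudo, p_slip)) >= 0),
            all(unlist(c(p_loss, p_pseudo, p_slip)) <= 1))
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

# per-branch event rate: scalar rates apply to every branch; named vectors
# are looked up by branch label (unlisted branches get 0)
rate_for <- function(rate, label) {
  if (is.null(names(rate))) return(unname(rate[1]))
  if (label %in% names(rate)) unname(rate[[label]]) else 0
}

# base probabilities on a strand: gc split between G and C with skew s
base_probs <- function(gc, skew) {
  c(A = (1 - gc) / 2, C = gc * (1 - skew) / 2, G = gc * (1 + skew) / 2,
    T = (1 - gc) / 2)
}

sample_bases <- function(n, probs) {
  if (n <= 0) return("")
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# sample n sense codons (no stops) as one string
sample_codons <- function(n, probs) {
  if (n <= 0) return("")
  m <- matrix(sample(names(probs), 3 * n, replace = TRUE, prob = probs),
              nrow = n)
  cods <- paste0(m[, 1], m[, 2], m[, 3])
  while (any(bad <- cods %in% STOP_CODONS)) {
    k <- sum(bad)
    m2 <- matrix(sample(names(probs), 3 * k, replace = TRUE, prob = probs),
                 nrow = k)
    cods[bad] <- paste0(m2[, 1], m2[, 2], m2[, 3])
  }
  paste(cods, collapse = "")
}

# rejecting stop codons (AT-rich words) pulls realized GC above the sampling
# GC; solve for the sampling GC whose accepted-codon composition hits the
# target
calibrate_gene_gc <- function(gc_target) {
  bases <- c("A", "C", "G", "T")
  codons <- as.matrix(expand.grid(bases, bases, bases, stringsAsFactors = FALSE))
  ngc <- rowSums(codons == "G" | codons == "C")
  is_stop <- apply(codons, 1, paste, collapse = "") %in% STOP_CODONS
  realized <- function(g) {
    p <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
    w <- p[codons[, 1]] * p[codons[, 2]] * p[codons[, 3]]
    w[is_stop] <- 0
    sum(w * ngc) / (3 * sum(w)) - gc_target
  }
  stats::uniroot(realized, c(1e-4, 0.9))$root
}

#' Simulate the ancestral genome
#'
#' Builds a circular genome of `n_genes` random stop-free CDS (ATG start,
#' TAA/TAG stop) separated by geometric spacers, at the target GC with the
#' configured GC-skew imposed by strand-asymmetric G/C placement switching
#' sign at the origin and its antipode. Long polyA/polyT tracts arise
#' naturally from the AT bias; palindromes are planted into spacers and
#' protected from later mutation (selection-maintained).
#'
#' @param cfg a [sim_config()].
#' @return list: `elements` (internal element tibble), `record`
#'   ([genome_record()] of the ancestor), `origin_pos`, `terminus_pos`,
#'   `palindromes` (tibble of planted palindromes, ancestor coordinates).
#' @export
simulate_ancestor <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_genes
  ncod <- pmax(60L, as.integer(round(rnorm(n, cfg$mean_cds_len / 3,
                                           cfg$mean_cds_len / 9))))
  gene_len <- 3L * ncod
  igs_len <- stats::rgeom(n, 1 / (cfg$igs_mean + 1))
  strands <- sample(c("+", "-"), n, replace = TRUE)
  total <- sum(gene_len) + sum(igs_len)
  if (total < 1000) stop("infeasible config: genome too small", call. = FALSE)
  origin <- round(cfg$origin_frac * total)
  terminus <- (origin + total %/% 2) %% total

  # genomic-strand skew sign at a position: +amp on [origin, terminus)
  skew_at <- function(pos) {
    on_leading <- ((pos - origin) %% total) < ((terminus - origin) %% total)
    if (on_leading) cfg$skew_amplitude else -cfg$skew_amplitude
  }

  gc_gene <- calibrate_gene_gc(cfg$gc_target)
  elements <- vector("list", 2L * n)
  pos <- 0
  for (i in seq_len(n)) {
    gl <- gene_len[i]
    s <- skew_at(pos + gl / 2)
    coding_skew <- if (strands[i] == "+") s else -s
    probs <- base_probs(gc_gene, coding_skew)
    body <- sample_codons(ncod[i] - 2L, probs)
    stopc <- sample(c("TAA", "TAG"), 1, prob = c(0.8, 0.2))
    elements[[2L * i - 1L]] <- list(
      type = "gene", family_id = sprintf("g%04d", i), strand = strands[i],
      seq = paste0("ATG", body, stopc), status = "intact", slip = NULL,
      protected = integer(0), anc_mid = pos + gl / 2)
    pos <- pos + gl
    il <- igs_len[i]
    s2 <- skew_at(pos + il / 2)
    elements[[2L * i]] <- list(
      type = "igs", family_id = NA_character_, strand = "+",
      seq = sample_bases(il, base_probs(cfg$gc_target, s2)),
      status = NA_character_, slip = NULL, protected = integer(0),
      anc_mid = pos + il / 2)
    pos <- pos + il
  }

  # plant palindromes into distinct spacers
  pals <- list()
  if (cfg$n_palindromes > 0) {
    igs_idx <- which(vapply(elements, function(e)
      e$type == "igs" && nchar(e$seq) >= 20, logical(1)))
    pick <- sample(igs_idx, min(cfg$n_palindromes, length(igs_idx)))
    for (j in pick) {
      arm_len <- sample(cfg$palindrome_arm[1]:cfg$palindrome_arm[2], 1)
      gap_len <- sample(cfg$palindrome_gap[1]:cfg$palindrome_gap[2], 1)
      probs <- base_probs(cfg$gc_target, 0)
      arm <- sample_bases(arm_len, probs)
      gap <- sample_bases(gap_len, probs)
      pal <- paste0(arm, gap, revcomp(arm))
      e <- elements[[j]]
      at <- nchar(e$seq) %/% 2
      e$seq <- paste0(substr(e$seq, 1, at), pal,
                      substr(e$seq, at + 1, nchar(e$seq)))
      e$protected <- union(e$protected, at + 0:(nchar(pal) - 1L))
      elements[[j]] <- e
      pals[[length(pals) + 1L]] <- tibble(
        element = j, offset_in_element = at, arm_length = arm_len,
        gap = gap_len, span = 2L * arm_len + gap_len)
    }
  }
  pal_tbl <- if (length(pals)) bind_rows(pals) else
    tibble(element = integer(), offset_in_element = integer(),
           arm_length = integer(), gap = integer(), span = integer())
  rec <- assemble_genome(elements, "ancestor", cfg)
  starts <- element_starts(elements)
  # ancestor coordinates of planted palindromes
  if (nrow(pal_tbl)) {
    pal_tbl$start <- starts[pal_tbl$element] + pal_tbl$offset_in_element
  } else pal_tbl$start <- integer(0)
  # element carrying the origin, for mapping it into descendant coordinates
  oel <- findInterval(origin, starts)
  list(elements = elements, record = rec, origin_pos = origin,
       terminus_pos = terminus, palindromes = pal_tbl,
       origin_element = oel, origin_offset = origin - starts[oel])
}

# genomic start coordinate of each element (literal, with slips applied)
element_starts <- function(elements) {
  lens <- vapply(elements, function(e) {
    nchar(e$seq) + if (!is.null(e$slip)) e$slip$sign else 0L
  }, numeric(1))
  cumsum(c(0, lens[-length(lens)]))
}

# materialize the literal sequence of an element (applying slippage indels)
literal_seq <- function(e) {
  s <- e$seq
  if (is.null(e$slip)) return(s)
  pos <- e$slip$pos
  if (e$slip$sign > 0) {
    paste0(substr(s, 1, pos), substr(s, pos + 1, pos + 1),
           substr(s, pos + 1, nchar(s)))
  } else {
    paste0(substr(s, 1, pos), substr(s, pos + 2, nchar(s)))
  }
}

# build a genome_record from an element list; minus-strand genes are laid
# down as the reverse complement of their stored coding-strand sequence
assemble_genome <- function(elements, id, cfg) {
  seqs <- vapply(elements, function(e) {
    s <- literal_seq(e)
    if (e$type == "gene" && e$strand == "-") revcomp(s) else s
  }, character(1))
  lens <- nchar(seqs)
  starts <- cumsum(c(0L, lens[-length(lens)]))
  feats <- list()
  k <- 0L
  for (i in seq_along(elements)) {
    e <- elements[[i]]
    if (e$type != "gene") next
    k <- k + 1L
    kind <- if (identical(e$status, "pseudo") && isTRUE(cfg$annotate_pseudo))
      "pseudogene" else "CDS"
    fs <- integer(0)
    if (!is.null(e$slip)) {
      fs <- as.integer(starts[i] +
        if (e$strand == "+") e$slip$pos else lens[i] - 1L - e$slip$pos)
    }
    feats[[k]] <- tibble(
      locus_tag = sprintf("%s_%04d", id, k), gene_name = "",
      kind = kind, start = as.integer(starts[i]),
      end = as.integer(starts[i] + lens[i]), strand = e$strand,
      frameshift_positions = list(fs))
  }
  feats <- if (length(feats)) bind_rows(feats) else empty_features()
  rec <- genome_record(id, paste(seqs, collapse = ""), feats,
                       is_circular = TRUE)
  # locus -> family map travels as an attribute (truth, not annotation)
  fam <- vapply(elements, function(e)
    if (e$type == "gene") e$family_id else NA_character_, character(1))
  attr(rec, "family_map") <- tibble(
    locus_tag = feats$locus_tag,
    family_id = fam[!is.na(fam)])
  rec
}

# mutate one element along a branch of length t (substitutions/site) under
# an F81-style model at the AT-biased equilibrium: a site with base a
# changes with probability (1 - pi_a)(1 - exp(-beta t)), beta = 1/(1 -
# sum(pi^2)), and the replacement is drawn from pi restricted to the other
# bases - this keeps the composition stationary at pi and the expected
# change count at t per site. A change that turns an internal gene codon
# into a stop is re-drawn among the remaining bases (reverted only if every
# alternative is a stop), so genes stay translatable in their stored frame.
mutate_element <- function(e, t, probs) {
  len <- nchar(e$seq)
  if (len == 0 || identical(e$status, "pseudo")) {
    return(list(e = e, n_sub = 0L, n_sites = 0L, n_expected = 0))
  }
  sites <- setdiff(seq_len(len) - 1L, e$protected)
  if (!length(sites)) return(list(e = e, n_sub = 0L, n_sites = 0L,
                                  n_expected = 0))
  chars <- seq_chars(e$seq)
  beta <- 1 / (1 - sum(probs^2))
  scale <- 1 - exp(-beta * t)
  p_site <- (1 - probs[chars[sites + 1L]]) * scale
  hit <- runif(length(sites)) < p_site
  n_expected <- sum(p_site)
  if (!any(hit)) {
    return(list(e = e, n_sub = 0L, n_sites = length(sites),
                n_expected = n_expected))
  }
  at <- sites[hit]
  orig <- chars
  old <- chars[at + 1L]
  new <- vapply(old, function(b) {
    pr <- probs[setdiff(names(probs), b)]
    sample(names(pr), 1, prob = pr)
  }, character(1))
  chars[at + 1L] <- new
  reverted <- 0L
  if (e$type == "gene") {
    for (ci in unique(at %/% 3L)) {
      if (3L * ci + 3L >= len) next  # terminal (stop) codon unconstrained
      span <- (3L * ci + 1L):(3L * ci + 3L)
      if (!paste(chars[span], collapse = "") %in% STOP_CODONS) next
      fixed <- FALSE
      sel <- at[at %/% 3L == ci]
      for (pos in sel[sample.int(length(sel))]) {
        alts <- setdiff(c("A", "C", "G", "T"),
                        c(chars[pos + 1L], orig[pos + 1L]))
        for (b in alts[sample.int(length(alts))]) {
          trial <- chars
          trial[pos + 1L] <- b
          if (!paste(trial[span], collapse = "") %in% STOP_CODONS) {
            chars <- trial; fixed <- TRUE; break
          }
        }
        if (fixed) break
      }
      if (!fixed) {  # give up: undo this codon's changes
        chars[sel + 1L] <- orig[sel + 1L]
        reverted <- reverted + length(sel)
      }
    }
  }
  e$seq <- paste(chars, collapse = "")
  list(e = e, n_sub = length(at) - reverted, n_sites = length(sites),
       n_expected = n_expected)
}

# plant a pseudogenization: one premature stop plus 0-2 small indels, then
# freeze the element (planted disruptions stay detectable)
plant_pseudo <- function(e) {
  ncod <- nchar(e$seq) %/% 3L
  stop_at <- sample(seq(max(2L, round(ncod * 0.25)),
                        max(3L, round(ncod * 0.75))), 1)
  chars <- seq_chars(e$seq)
  chars[(3L * (stop_at - 1L) + 1L):(3L * (stop_at - 1L) + 3L)] <-
    c("T", "A", "A")
  s <- paste(chars, collapse = "")
  n_extra <- sample(0:2, 1)
  if (n_extra > 0) {
    for (k in seq_len(n_extra)) {
      at <- sample(seq(round(nchar(s) * 0.25), round(nchar(s) * 0.75)), 1)
      if (runif(1) < 0.5) {
        s <- paste0(substr(s, 1, at), substr(s, at + 2, nchar(s)))
      } else {
        s <- paste0(substr(s, 1, at), substr(s, at, at), substr(s, at + 1, nchar(s)))
      }
    }
  }
  e$seq <- s
  e$status <- "pseudo"
  e$n_disruptions <- 1L + n_extra
  e
}

# plant a slippage frameshift in a random qualifying tract
plant_slip <- function(e, min_tract) {
  tr <- find_homopolymers(e$seq, c("A", "T"), min_len = min_tract)
  # keep clear of the start/stop codons
  tr <- tr[tr$start >= 3 & tr$start + tr$length <= nchar(e$seq) - 3, ]
  if (!nrow(tr)) return(NULL)
  i <- sample(nrow(tr), 1)
  sign <- sample(c(1L, -1L), 1)
  pos <- tr$start[i] + sample(tr$length[i], 1) - 1L  # 0-based, inside tract
  e$slip <- list(pos = pos, sign = sign, tract_base = tr$base[i],
                 tract_len = tr$length[i] + as.integer(sign > 0))
  e$protected <- union(e$protected,
                       (tr$start[i] - 1L):(tr$start[i] + tr$length[i]))
  list(e = e, tract_start = tr$start[i], tract_len = tr$length[i],
       pos = pos, sign = sign, base = tr$base[i])
}

#' Evolve an ancestral genome along a rooted tree
#'
#' Walks the tree from the root, applying per-branch substitutions (per-site
#' probability `3/4 (1 - exp(-4t/3))` for branch length `t`, AT-biased
#' replacement), gene losses (the gene is replaced by a scar spacer keeping a
#' `Uniform(0, scar_frac)` fraction of its sequence), pseudogenizations and
#' slippage frameshifts, plus the configured hotspot of extra losses near
#' the origin. Gene order and strand are preserved. Every event is recorded
#' in the truth manifest.
#'
#' @param anc result of [simulate_ancestor()].
#' @param cfg the [sim_config()] used for the ancestor.
#' @return list: `genomes` (named list of leaf [genome_record()]s),
#'   `ancestor`, `manifest` (list: `events`, `palindromes`, `origin_pos`,
#'   `terminus_pos`, `substitutions`, `family_maps`, `tree`).
#' @export
evolve_tree <- function(anc, cfg) {
  ti <- tree_info(cfg$tree)
  tree <- ti$tree
  hotspot_branch <- cfg$hotspot_branch %||% tree$tip.label[1]
  events <- list()
  subs <- list()
  leaves <- list()
  total <- sum(vapply(anc$elements, function(e) nchar(e$seq), numeric(1)))
  # leaves whose copy of a family an event has already touched. An event is
  # skipped when it would (i) leave no pristine copy in any leaf - with no
  # intact reference the family could not be classified - or (ii) make the
  # affected leaves exactly a clade larger than the event's own branch:
  # e.g. independent losses on two sister leaves are indistinguishable from
  # a single stem loss under Dollo parsimony, so planting them would make
  # the manifest unrecoverable in principle
  affected <- new.env(parent = emptyenv())
  would_confound <- function(fam, leafset) {
    prior <- get0(fam, envir = affected, ifnotfound = character(0))
    new_set <- union(prior, leafset)
    if (length(new_set) >= ti$ntip) return(TRUE)
    lab <- paste(sort(new_set), collapse = "+")
    lab %in% ti$labels && length(new_set) > length(leafset)
  }
  mark_affected <- function(fam, leafset) {
    prior <- get0(fam, envir = affected, ifnotfound = character(0))
    assign(fam, union(prior, leafset), envir = affected)
  }

  apply_branch <- function(elements, t, label) {
    probs <- base_probs(cfg$gc_target, 0)
    n_sub <- 0L; n_sites <- 0L; n_expected <- 0
    for (i in seq_along(elements)) {
      m <- mutate_element(elements[[i]], t, probs)
      elements[[i]] <- m$e
      n_sub <- n_sub + m$n_sub; n_sites <- n_sites + m$n_sites
      n_expected <- n_expected + m$n_expected
    }
    subs[[length(subs) + 1L]] <<- tibble(branch = label,
                                         n_sites = n_sites,
                                         n_expected = n_expected,
                                         n_sub = n_sub)
    # events on genes still intact and unslipped
    gidx <- which(vapply(elements, function(e)
      e$type == "gene" && identical(e$status, "intact") && is.null(e$slip),
      logical(1)))
    if (length(gidx)) {
      pl <- rate_for(cfg$p_loss, label)
      pp <- rate_for(cfg$p_pseudo, label)
      psl <- rate_for(cfg$p_slip, label)
      u <- runif(length(gidx))
      ev <- ifelse(u < pl, "LOSS",
            ifelse(u < pl + pp, "EROSION",
            ifelse(u < pl + pp + psl, "FRAMESHIFT", "none")))
      # hotspot: extra losses in a window centred on the origin
      if (label == hotspot_branch && cfg$hotspot_losses > 0) {
        mid <- vapply(elements[gidx], function(e) e$anc_mid, numeric(1))
        inwin <- circular_dist(mid, anc$origin_pos, total) <=
          cfg$hotspot_width / 2
        cand <- which(inwin & ev == "none")
        extra <- head(cand[sample.int(length(cand))], cfg$hotspot_losses)
        ev[extra] <- "LOSS"
      }
      branch_leaves <- ti$desc[[match(label, ti$labels)]]
      for (k in seq_along(gidx)) {
        if (ev[k] == "none") next
        i <- gidx[k]
        e <- elements[[i]]
        if (would_confound(e$family_id, branch_leaves)) next
        if (ev[k] == "LOSS") {
          keep <- floor(runif(1, 0, cfg$scar_frac) * nchar(e$seq))
          elements[[i]] <- list(type = "igs", family_id = NA_character_,
                                strand = "+",
                                seq = substr(e$seq, 1, keep),
                                status = NA_character_, slip = NULL,
                                protected = integer(0), anc_mid = e$anc_mid)
          events[[length(events) + 1L]] <<- tibble(
            branch = label, family_id = e$family_id, event = "LOSS",
            detail = NA_character_)
          mark_affected(e$family_id, branch_leaves)
        } else if (ev[k] == "EROSION") {
          elements[[i]] <- plant_pseudo(e)
          events[[length(events) + 1L]] <<- tibble(
            branch = label, family_id = e$family_id, event = "EROSION",
            detail = sprintf("disruptions=%d", elements[[i]]$n_disruptions))
          mark_affected(e$family_id, branch_leaves)
        } else {
          ps <- plant_slip(e, cfg$slip_min_tract)
          if (!is.null(ps)) {
            elements[[i]] <- ps$e
            events[[length(events) + 1L]] <<- tibble(
              branch = label, family_id = e$family_id, event = "FRAMESHIFT",
              detail = sprintf("pos=%d;sign=%+d;base=%s;tract=%d",
                               ps$pos, ps$sign, ps$base, ps$tract_len))
            mark_affected(e$family_id, branch_leaves)
          }
        }
      }
    }
    elements
  }

  walk <- function(node, elements) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    for (ch in kids) {
      t <- tree$edge.length[which(tree$edge[, 1] == node & tree$edge[, 2] == ch)]
      el2 <- apply_branch(elements, t, ti$labels[ch])
      if (ch <= ti$ntip) leaves[[tree$tip.label[ch]]] <<- el2
      else walk(ch, el2)
    }
  }
  walk(ti$root, anc$elements)

  genomes <- lapply(names(leaves), function(nm)
    assemble_genome(leaves[[nm]], nm, cfg))
  names(genomes) <- names(leaves)
  genomes <- genomes[tree$tip.label]
  # origin position mapped into each leaf's coordinates (indels and
  # deletions upstream of the origin shift it)
  origin_by_genome <- vapply(tree$tip.label, function(nm) {
    el <- leaves[[nm]]
    starts <- element_starts(el)
    lens <- vapply(el, function(e)
      nchar(e$seq) + if (!is.null(e$slip)) e$slip$sign else 0L, numeric(1))
    starts[anc$origin_element] +
      min(anc$origin_offset, lens[anc$origin_element])
  }, numeric(1))
  # planted palindromes mapped into each leaf (spacer elements never change
  # length, so the within-element offset is stable)
  palindromes_by_genome <- bind_rows(lapply(tree$tip.label, function(nm) {
    if (!nrow(anc$palindromes)) return(NULL)
    starts <- element_starts(leaves[[nm]])
    mutate(anc$palindromes, genome = nm,
           start = as.integer(starts[.data$element] + .data$offset_in_element))
  }))
  family_maps <- bind_rows(lapply(names(genomes), function(nm)
    mutate(attr(genomes[[nm]], "family_map"), genome = nm)))
  manifest <- list(
    events = if (length(events)) bind_rows(events) else
      tibble(branch = character(), family_id = character(),
             event = character(), detail = character()),
    palindromes = anc$palindromes,
    origin_pos = anc$origin_pos, terminus_pos = anc$terminus_pos,
    origin_by_genome = origin_by_genome,
    palindromes_by_genome = palindromes_by_genome,
    substitutions = bind_rows(subs),
    family_maps = family_maps,
    tree = ape::write.tree(tree))
  list(genomes = genomes, ancestor = anc$record, manifest = manifest)
}

#' Simulate a genome triad with its truth manifest
#'
#' Convenience wrapper: [simulate_ancestor()] then [evolve_tree()].
#'
#' @param cfg a [sim_config()].
#' @return see [evolve_tree()].
#' @export
simulate_triad <- function(cfg) {
  anc <- simulate_ancestor(cfg)
  evolve_tree(anc, cfg)
}

#' Write a simulated fixture to disk
#'
#' GenBank + FASTA per genome, the tree as newick, and the manifest as JSON;
#' everything is plain text and regenerates byte-identically from the same
#' configuration.
#'
#' @param sim result of [simulate_triad()] / [evolve_tree()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(sim$genomes)) {
    write_genbank(sim$genomes[[nm]], file.path(dir, paste0(nm, ".gb")))
    write_genome_fasta(sim$genomes[[nm]], file.path(dir, paste0(nm, ".fasta")))
  }
  writeLines(sim$manifest$tree, file.path(dir, "tree.nwk"))
  m <- sim$manifest
  jsonlite::write_json(
    list(events = m$events, palindromes = m$palindromes,
         origin_pos = m$origin_pos, terminus_pos = m$terminus_pos,
         origin_by_genome = as.list(m$origin_by_genome),
         substitutions = m$substitutions, family_maps = m$family_maps,
         tree = m$tree),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
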