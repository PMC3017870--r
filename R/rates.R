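# Nei-Gojobori (1986) machinery. Site fractions and pathway-averaged
# difference counts are tabulated once per session; convention: substitutions
# to stop codons count as nonsynonymous in the site fractions, and mutational
# pathways passing through a stop codon get zero weight (all-blocked pairs
# fall back to equal path weights with stop steps counted nonsynonymous).
.ng_env <- new.env(parent = emptyenv())

ng_tables <- function() {
  if (!is.null(.ng_env$syn_sites)) return(.ng_env)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  bases <- c("A", "C", "G", "T")
  is_stop <- gc == "*"
  syn_sites <- setNames(numeric(64), codons)
  for (cd in codons) {
    if (is_stop[cd]) { syn_sites[cd] <- NA_real_; next }
    s <- 0
    for (k in 1:3) {
      for (b in setdiff(bases, substr(cd, k, k))) {
        alt <- cd
        substr(alt, k, k) <- b
        if (!is_stop[alt] && gc[alt] == gc[cd]) s <- s + 1 / 3
      }
    }
    syn_sites[cd] <- s
  }
  # pathway-averaged synonymous/nonsynonymous differences per codon pair
  sd_tab <- matrix(0, 64, 64, dimnames = list(codons, codons))
  nd_tab <- matrix(0, 64, 64, dimnames = list(codons, codons))
  perms <- list(`1` = list(1L),
                `2` = list(c(1L, 2L), c(2L, 1L)),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  step_class <- function(c1, c2) {
    # one-base step c1 -> c2: synonymous or nonsynonymous; steps touching a
    # stop codon are nonsynonymous (only used in the all-blocked fallback)
    if (!is_stop[c1] && !is_stop[c2] && gc[c1] == gc[c2]) "s" else "n"
  }
  for (c1 in codons) {
    if (is_stop[c1]) next
    for (c2 in codons) {
      if (is_stop[c2] || c1 == c2) next
      diffpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
      d <- length(diffpos)
      paths <- perms[[as.character(d)]]
      tally <- function(include_blocked) {
        sd <- 0; nd <- 0; used <- 0
        for (p in paths) {
          cur <- c1; ps <- 0; pn <- 0; blocked <- FALSE
          for (k in diffpos[p]) {
            nxt <- cur
            substr(nxt, k, k) <- substr(c2, k, k)
            if (is_stop[nxt] && nxt != c2) blocked <- TRUE
            if (step_class(cur, nxt) == "s") ps <- ps + 1 else pn <- pn + 1
            cur <- nxt
          }
          if (blocked && !include_blocked) next
          sd <- sd + ps; nd <- nd + pn; used <- used + 1
        }
        list(sd = sd, nd = nd, used = used)
      }
      t1 <- tally(FALSE)
      if (t1$used == 0) t1 <- tally(TRUE)
      sd_tab[c1, c2] <- t1$sd / t1$used
      nd_tab[c1, c2] <- t1$nd / t1$used
    }
  }
  .ng_env$syn_sites <- syn_sites
  .ng_env$sd_tab <- sd_tab
  .ng_env$nd_tab <- nd_tab
  .ng_env$is_stop <- is_stop
  .ng_env
}

# split an aligned (or plain) codon sequence into codon triplets
split_codons <- function(nt) {
  nt <- toupper(nt)
  n <- nchar(nt)
  if (n %% 3 != 0) stop("sequence length not divisible by 3", call. = FALSE)
  substring(nt, seq(1, n, 3), seq(3, n, 3))
}

#' Pairwise nonsynonymous distance (Nei-Gojobori)
#'
#' NG86 counting: nonsynonymous sites averaged over both sequences,
#' pathway-averaged nonsynonymous differences, and a Jukes-Cantor correction
#' `dN = -(3/4) log(1 - (4/3) pN)`. Codon columns containing a gap, an N, or
#' a stop codon in either sequence are excluded (pairwise deletion).
#'
#' @param a,b aligned codon sequences of equal length (gaps as `-`).
#' @param min_codons minimum comparable codons required.
#' @return one-row tibble: `dn`, `pn`, `n_sites`, `n_diffs`, `n_codons`,
#'   `saturated` (`dn` is `Inf` when `pN >= 3/4`).
#' @export
pairwise_dn <- function(a, b, min_codons = 10L) {
  env <- ng_tables()
  ca <- split_codons(a); cb <- split_codons(b)
  if (length(ca) != length(cb)) stop("aligned lengths differ", call. = FALSE)
  ok <- !grepl("[-N]", ca) & !grepl("[-N]", cb)
  ok[ok] <- !env$is_stop[ca[ok]] & !env$is_stop[cb[ok]]
  ca <- ca[ok]; cb <- cb[ok]
  if (length(ca) < min_codons) {
    stop("fewer than ", min_codons, " comparable codons", call. = FALSE)
  }
  syn <- (sum(env$syn_sites[ca]) + sum(env$syn_sites[cb])) / 2
  n_sites <- 3 * length(ca) - syn
  idx <- cbind(ca, cb)
  nd <- sum(env$nd_tab[idx])
  pn <- nd / n_sites
  saturated <- pn >= 3 / 4
  dn <- if (saturated) Inf else -3 / 4 * log(1 - 4 / 3 * pn)
  tibble(dn = dn, pn = pn, n_sites = n_sites, n_diffs = nd,
         n_codons = length(ca), saturated = saturated)
}

#' Codon-aware pairwise alignment
#'
#' Translates two CDS, aligns the proteins globally (Needleman-Wunsch,
#' BLOSUM62, affine gaps) and back-translates to a codon alignment. Terminal
#' stop codons are stripped first; an internal stop is an error (families
#' with uncorrected disruptions are excluded from rate estimation upstream).
#'
#' @param nt_a,nt_b CDS nucleotide strings (coding strand), lengths divisible
#'   by 3.
#' @return list with aligned codon strings `a` and `b` (gaps `---`).
#' @export
codon_align <- function(nt_a, nt_b) {
  prep <- function(nt) {
    cs <- split_codons(nt)
    if (length(cs) && cs[length(cs)] %in% STOP_CODONS) cs <- cs[-length(cs)]
    aa <- translate_cds(paste(cs, collapse = ""))
    if (grepl("\\*", aa)) stop("internal stop codon", call. = FALSE)
    list(codons = cs, aa = aa)
  }
  pa <- prep(nt_a); pb <- prep(nt_b)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa$aa), Biostrings::AAString(pb$aa),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  back <- function(aligned_aa, codons) {
    cols <- strsplit(aligned_aa, "")[[1]]
    out <- character(length(cols))
    j <- 0L
    for (i in seq_along(cols)) {
      if (cols[i] == "-") out[i] <- "---"
      else { j <- j + 1L; out[i] <- codons[j] }
    }
    paste(out, collapse = "")
  }
  list(a = back(as.character(Biostrings::alignedPattern(al)), pa$codons),
       b = back(as.character(Biostrings::alignedSubject(al)), pb$codons))
}

#' Three-point branch decomposition of pairwise distances
#'
#' Given pairwise distances between two ingroup taxa (1, 2) and an outgroup
#' (3), solves the additive three-taxon tree: `K1 = (d12 + d13 - d23)/2` is
#' the branch length from taxon 1 back to its ancestor with taxon 2, `K2 =
#' (d12 + d23 - d13)/2` the branch to taxon 2. Negative solutions (sampling
#' noise at low divergence) are clipped to 0 and flagged; the rate
#' fold-increase `fold = K1/K2` is undefined when K2 is 0 or any input is
#' saturated.
#'
#' @param d12,d13,d23 nonnegative distances (vectorized).
#' @return tibble: `K1`, `K2`, `fold`, `clipped`, `defined`.
#' @export
branch_decompose <- function(d12, d13, d23) {
  k1 <- (d12 + d13 - d23) / 2
  k2 <- (d12 + d23 - d13) / 2
  saturated <- !is.finite(d12) | !is.finite(d13) | !is.finite(d23)
  clipped <- (k1 < 0 | k2 < 0) & !saturated
  k1 <- pmax(k1, 0); k2 <- pmax(k2, 0)
  k1[saturated] <- NA_real_; k2[saturated] <- NA_real_
  fold <- ifelse(!saturated & !clipped & k2 > 0, k1 / k2, NA_real_)
  tibble(K1 = k1, K2 = k2, fold = fold, clipped = clipped,
         defined = !is.na(fold))
}

#' Summarise per-gene rate fold-increases
#'
#' @param triples tibble with a `fold` column (NA = undefined).
#' @return one-row tibble: `median_fold`, `min_fold`, `max_fold`, `n_defined`,
#'   `n_undefined`.
#' @export
fold_summary <- function(triples) {
  f <- triples$fold[!is.na(triples$fold)]
  if (!length(f)) stop("no defined fold values", call. = FALSE)
  tibble(median_fold = median(f), min_fold = min(f), max_fold = max(f),
         n_defined = length(f), n_undefined = sum(is.na(triples$fold)))
}

# undo a single-base slippage indel so a gene can be treated as intact:
# sign +1 = the gene carries an inserted base at 0-based position pos
# (remove it); sign -1 = a deleted base (re-insert a copy of the tract base)
slip_correct <- function(nt, pos, sign) {
  if (sign > 0) {
    paste0(substr(nt, 1, pos), substr(nt, pos + 2, nchar(nt)))
  } else {
    base <- substr(nt, pos + 1, pos + 1)
    paste0(substr(nt, 1, pos + 1), base, substr(nt, pos + 2, nchar(nt)))
  }
}

#' Per-gene nonsynonymous rate comparison across a genome triad
#'
#' For every family with a usable CDS in all three genomes, computes the
#' three pairwise dN values from codon-aware alignments, decomposes them on
#' the rooted triplet with `outgroup` as taxon 3, and reports the per-gene
#' fold-increase K1/K2 for `lineage1` relative to `lineage2`. Genes whose
#' only defect is a single slippage frameshift are corrected with the
#' supplied calls and treated as intact; genes with internal stops after
#' correction are excluded.
#'
#' @param table an `ortholog_table`.
#' @param genomes named list of [genome_record()]s.
#' @param lineage1,lineage2 genome ids of the two ingroup lineages.
#' @param outgroup genome id of the outgroup.
#' @param frameshift_calls optional tibble from
#'   [detect_slippage_frameshifts()] used to correct single tract indels.
#' @param min_codons minimum comparable codons per pair.
#' @return tibble: `family_id`, `d12`, `d13`, `d23`, `K1`, `K2`, `fold`,
#'   `clipped`, `defined`.
#' @export
rate_triples <- function(table, genomes, lineage1, lineage2, outgroup,
                         frameshift_calls = NULL, min_codons = 10L) {
  gids <- c(lineage1, lineage2, outgroup)
  stopifnot(all(gids %in% attr(table, "genomes") %||% unique(table$genome)))
  wide <- tidyr::pivot_wider(table, id_cols = "family_id",
                             names_from = "genome", values_from = "locus_tag")
  kinds <- table |> select("genome", "locus_tag", "kind")
  get_seq <- function(gid, locus) {
    rec <- genomes[[gid]]
    i <- which(rec$features$locus_tag == locus)
    nt <- feature_seq(rec, i)
    if (!is.null(frameshift_calls) && nrow(frameshift_calls)) {
      fc <- frameshift_calls[frameshift_calls$genome == gid &
                               frameshift_calls$locus_tag == locus, ]
      if (nrow(fc) == 1) nt <- slip_correct(nt, fc$indel_pos[1], fc$indel_sign[1])
    }
    nt <- substr(nt, 1, nchar(nt) - nchar(nt) %% 3)
    nt
  }
  rows <- lapply(seq_len(nrow(wide)), function(i) {
    loci <- vapply(gids, function(g) wide[[g]][i] %||% NA_character_,
                   character(1))
    if (any(is.na(loci))) return(NULL)
    kind_ok <- vapply(seq_along(gids), function(j) {
      k <- kinds$kind[kinds$genome == gids[j] & kinds$locus_tag == loci[j]]
      length(k) == 1 && k == "CDS"
    }, logical(1))
    if (!all(kind_ok)) return(NULL)
    seqs <- tryCatch(lapply(seq_along(gids), function(j) get_seq(gids[j], loci[j])),
                     error = function(e) NULL)
    if (is.null(seqs)) return(NULL)
    dn_pair <- function(a, b) {
      al <- tryCatch(codon_align(a, b), error = function(e) NULL)
      if (is.null(al)) return(NA_real_)
      tryCatch(pairwise_dn(al$a, al$b, min_codons)$dn, error = function(e) NA_real_)
    }
    d12 <- dn_pair(seqs[[1]], seqs[[2]])
    d13 <- dn_pair(seqs[[1]], seqs[[3]])
    d23 <- dn_pair(seqs[[2]], seqs[[3]])
    if (any(is.na(c(d12, d13, d23)))) return(NULL)
    bd <- branch_decompose(d12, d13, d23)
    tibble(family_id = wide$family_id[i], d12 = d12, d13 = d13, d23 = d23,
           K1 = bd$K1, K2 = bd$K2, fold = bd$fold, clipped = bd$clipped,
           defined = bd$defined)
  })
  bind_rows(rows[!vapply(rows, is.null, logical(1))])
}
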