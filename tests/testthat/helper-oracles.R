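# Independent oracles used to cross-check the package implementations.

# random DNA string with the given base weights
random_dna <- function(n, probs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# homopolymer tracts via the regex engine (independent of the rle scan)
oracle_homopolymers <- function(seq, bases = c("A", "T"), min_len = 9L) {
  rows <- lapply(bases, function(b) {
    m <- gregexpr(sprintf("%s{%d,}", b, min_len), seq)[[1]]
    if (m[1] == -1) return(NULL)
    data.frame(base = b, start = as.integer(m) - 1L,
               length = attr(m, "match.length"))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(base = character(), start = integer(),
                      length = integer()))
  }
  out[order(out$start), , drop = FALSE]
}

# exhaustive IUPAC motif match on both strands, by expanding the pattern to
# a regular expression over every window
oracle_iupac_hits <- function(seq, pattern) {
  iupac <- Biostrings::IUPAC_CODE_MAP
  to_re <- function(p) paste(vapply(strsplit(p, "")[[1]], function(ch) {
    e <- iupac[[ch]]
    if (nchar(e) == 1) e else paste0("[", e, "]")
  }, character(1)), collapse = "")
  hits <- function(p, strand) {
    re <- to_re(p)
    n <- nchar(seq); w <- nchar(p)
    at <- which(vapply(seq_len(n - w + 1),
                       function(i) grepl(paste0("^", re, "$"),
                                         substr(seq, i, i + w - 1)),
                       logical(1)))
    if (!length(at)) return(NULL)
    data.frame(start = at - 1L, strand = strand)
  }
  out <- rbind(hits(pattern, "+"), hits(revcomp(pattern), "-"))
  if (is.null(out)) return(data.frame(start = integer(), strand = character()))
  out[order(out$start, out$strand), , drop = FALSE]
}

# brute-force inverted-repeat search on one antidiagonal at a time; same
# output contract as the compiled scanner, written independently in R
oracle_palindromes <- function(seq, min_arm = 30L, max_arm = 1000L,
                               max_gap = 20L, max_mismatch = 3L) {
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)
  comp <- c(4L, 3L, 2L, 1L, 5L)
  x <- unname(code[strsplit(toupper(seq), "")[[1]]])
  n <- length(x)
  is_match <- function(p, q) x[p] != 5L && x[q] != 5L && x[p] == comp[x[q]]
  rows <- list()
  for (s in 2:(2L * n - 2L)) {   # 1-based: p + q = s + 1 in 0-based terms
    p_hi <- s %/% 2L             # inner arm1 position (1-based), q = s+1-p
    for (p in p_hi:max(1L, ceiling((s - max_gap) / 2))) {
      q <- s + 1L - p
      if (q > n) break
      gap <- q - p - 1L
      if (gap < 0L || gap > max_gap) next
      if (!is_match(p, q)) next
      if (gap >= 2L && is_match(p + 1L, q - 1L)) next  # extendable inward
      mm <- 0L; last_good <- 0L; mm_at_good <- 0L
      k <- 1L
      while (p - k >= 1L && q + k <= n && k + 1L <= max_arm) {
        if (is_match(p - k, q + k)) {
          last_good <- k; mm_at_good <- mm
        } else {
          mm <- mm + 1L
          if (mm > max_mismatch) break
        }
        k <- k + 1L
      }
      arm <- last_good + 1L
      if (arm < min_arm) next
      rows[[length(rows) + 1L]] <- data.frame(
        arm1_start = p - last_good - 1L, arm2_start = q - 1L,
        arm_length = arm, gap = gap, mismatches = mm_at_good)
    }
  }
  if (!length(rows)) {
    return(data.frame(arm1_start = integer(), arm2_start = integer(),
                      arm_length = integer(), gap = integer(),
                      mismatches = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$arm1_start, out$arm2_start), , drop = FALSE]
}

# quadratic-space Gotoh local alignment (BLOSUM62, affine gaps), scores only
oracle_sw_score <- function(a, b, gap_open = 11, gap_ext = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  sub <- get("BLOSUM62", envir = environment())
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- X <- Y <- matrix(-Inf, n + 1, m + 1)
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_ext,
                     X[i - 1, j] - gap_ext)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_ext,
                     Y[i, j - 1] - gap_ext)
      sc <- sub[av[i - 1], bv[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1] + sc, X[i, j] + 0, Y[i, j] + 0)
      # local model: alignment may end in a gap state but that never helps
      best <- max(best, M[i, j])
    }
  }
  best
}

# independent Nei-Gojobori: per-codon site fractions and pathway-averaged
# differences computed by direct recursion (no precomputed tables)
oracle_dn <- function(a, b) {
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  is_stop <- function(cd) gc[[cd]] == "*"
  syn_sites <- function(cd) {
    s <- 0
    for (k in 1:3) for (bb in setdiff(bases, substr(cd, k, k))) {
      alt <- cd; substr(alt, k, k) <- bb
      if (!is_stop(alt) && gc[[alt]] == gc[[cd]]) s <- s + 1 / 3
    }
    s
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  path_counts <- function(c1, c2, allow_stops) {
    dp <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    sd <- 0; nd <- 0; used <- 0
    for (ord in perms(dp)) {
      cur <- c1; ps <- 0; pn <- 0; blocked <- FALSE
      for (k in ord) {
        nxt <- cur; substr(nxt, k, k) <- substr(c2, k, k)
        if (is_stop(nxt) && nxt != c2) blocked <- TRUE
        syn <- !is_stop(cur) && !is_stop(nxt) && gc[[cur]] == gc[[nxt]]
        if (syn) ps <- ps + 1 else pn <- pn + 1
        cur <- nxt
      }
      if (blocked && !allow_stops) next
      sd <- sd + ps; nd <- nd + pn; used <- used + 1
    }
    list(sd = sd, nd = nd, used = used)
  }
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  keep <- !vapply(ca, is_stop, logical(1)) & !vapply(cb, is_stop, logical(1))
  ca <- ca[keep]; cb <- cb[keep]
  syn <- (sum(vapply(ca, syn_sites, numeric(1))) +
            sum(vapply(cb, syn_sites, numeric(1)))) / 2
  n_sites <- 3 * length(ca) - syn
  nd <- 0
  for (i in seq_along(ca)) {
    if (ca[i] == cb[i]) next
    pc <- path_counts(ca[i], cb[i], FALSE)
    if (pc$used == 0) pc <- path_counts(ca[i], cb[i], TRUE)
    nd <- nd + pc$nd / pc$used
  }
  pn <- nd / n_sites
  if (pn >= 3 / 4) return(Inf)
  -3 / 4 * log(1 - 4 / 3 * pn)
}

# random sense codon sequence (no stops anywhere)
random_codons <- function(n_codons, probs = c(A = .3, C = .2, G = .2, T = .3)) {
  stops <- c("TAA", "TAG", "TGA")
  cods <- character(n_codons)
  for (i in seq_len(n_codons)) {
    repeat {
      cd <- paste(sample(names(probs), 3, TRUE, probs), collapse = "")
      if (!cd %in% stops) break
    }
    cods[i] <- cd
  }
  paste(cods, collapse = "")
}

# exhaustive minimal-event Dollo search on the rooted triplet ((A,B),C):
# enumerate severities of the two internal nodes, minimal changed-edge
# count, ties by the lowest internal severities (leafward placement)
oracle_dollo3 <- function(states, tipnames = names(states)) {
  sev_of <- c(INTACT = 0L, FRAMESHIFT_SLIPPAGE = 0L, PSEUDOGENE = 1L,
              ABSENT = 2L)
  sv <- sev_of[states]
  if (all(sv == 2L)) {
    return(list(present = FALSE,
                events = data.frame(branch = character(),
                                    event = character())))
  }
  lab <- c(tipnames[1], tipnames[2], tipnames[3],
           paste(sort(tipnames[1:2]), collapse = "+"))
  best <- NULL; bestkey <- c(Inf, Inf)
  for (root in 0:2) for (anc in 0:2) {
    if (root > anc || anc > sv[1] || anc > sv[2] || root > sv[3]) next
    d <- c(sv[1] - anc, sv[2] - anc, sv[3] - root, anc - root)
    key <- c(sum(d > 0), root + anc)
    if (key[1] < bestkey[1] ||
        (key[1] == bestkey[1] && key[2] < bestkey[2])) {
      bestkey <- key
      ev <- data.frame(branch = lab[d > 0],
                       to = c(sv[1], sv[2], sv[3], anc)[d > 0])
      best <- list(root = root, anc = anc, ev = ev)
    }
  }
  events <- data.frame(branch = best$ev$branch,
                       event = ifelse(best$ev$to == 2L, "LOSS", "EROSION"))
  list(present = TRUE, events = events[order(events$branch), , drop = FALSE],
       root = best$root)
}

# exact two-sided rank-sum p by full enumeration of group assignments
oracle_ranksum_exact <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  sel <- combn(n, n1)
  Ws <- colSums(matrix(r[sel], nrow = n1))
  mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
}

# tiny simulated triad shared by several test files (built once per run)
small_triad <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 4021, n_genes = 60, hotspot_losses = 0,
                        n_palindromes = 4,
                        p_loss = 0.04, p_pseudo = 0.02, p_slip = 0.08)
      sim <- simulate_triad(cfg)
      tab <- suppressMessages(build_ortholog_table(sim$genomes))
      st <- suppressWarnings(assign_gene_states(tab, sim$genomes))
      cache <<- list(cfg = cfg, sim = sim, table = tab, states = st)
    }
    cache
  }
})

# a small sub-genome (first n genes) for tests that only need a toy record
subset_record <- function(rec, n_feats) {
  f <- rec$features[seq_len(n_feats), ]
  end <- max(f$end) + 50L
  genome_record(rec$id, substr(rec$sequence, 1, end), f, is_circular = FALSE)
}
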