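---
title: "Methods: comparative analysis of endosymbiont genome reduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of endosymbiont genome reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reducta)
```

# The problem

Obligate intracellular bacteria such as *Blochmannia*, the mutualist of
camponotine ants, undergo genome reduction: small effective population
sizes, relaxed selection on host-provided functions and a pervasive
deletional bias erode genes into pseudogenes and eventually delete them.
Comparing two or three closely related endosymbiont genomes with strictly
conserved gene order makes the process directly observable: each gene
family can be classified per genome as intact, slippage-frameshifted,
pseudogenized or absent, and the events polarized on the species tree.

`reducta` implements this comparative workflow end to end: ortholog table
construction, gene-state classification, Dollo polarization, deletion
hotspot detection, homopolymer-slippage frameshift calls, replication
origin prediction from GC skew, palindrome and dnaA-box scans, intergenic
spacer (IGS) analysis, and lineage-specific nonsynonymous rate
comparisons. A seeded simulator generates genome triads with a truth
manifest so that every stage is testable without external data.

# Gene states and their classification

A family member is compared to an intact reference member (a full-length,
stop-free CDS from another genome) and assigned one of four states, in
increasing severity:

* `INTACT` — full-length, in frame, no internal stops;
* `FRAMESHIFT_SLIPPAGE` — exactly one 1-bp indel inside a polyA/polyT
  tract of at least `min_tract` bp (default 7) whose conceptual correction
  restores a stop-free, in-frame ORF. Transcriptional slippage can restore
  the reading frame of such genes at the mRNA level, so they are treated
  as functionally intact throughout;
* `PSEUDOGENE` — internal stops not attributable to a single tract indel,
  two or more frame disruptions, or aligned coverage below
  `min_coverage` (default 0.6, matching the presence-screen convention);
* `ABSENT` — no annotated locus and no residual homology in the
  corresponding intergenic region.

A numerical point that shaped the implementation: global DNA alignments
of extremely AT-biased, low-complexity genes frequently acquire spurious
compensating 1-bp gap pairs, because realigning a short segment by one
position can "pay" for two gap openings in a homopolymer-rich context.
The classifier therefore never counts raw alignment gaps as evidence.
The load-bearing signals are frame integrity (sequence length modulo 3)
and internal stop codons; the alignment is used only to locate candidate
slippage indels and to measure truncation. For the same reason the
slippage test scans all qualifying tracts within 20 bp of the aligned
indel position — gap placement floats freely inside and around
homopolymer tracts — and accepts the candidate whose correction yields a
stop-free in-frame ORF.

Members missing from the annotation are screened by six-frame local
protein alignment of the corresponding intergenic region (located between
the nearest flanking families present in the genome, capped at 10 kb)
against the reference protein: a hit covering at least 60% of the
reference at an e-value-like score below 1e-5 is evidence of an
unannotated eroded gene (`PSEUDOGENE`), otherwise the family is `ABSENT`.
RNA genes are scored by presence/absence only.

# Ortholog table

Families are seeded by pairwise reciprocal best hits (Smith–Waterman,
BLOSUM62, affine gaps 11/1, via Biostrings) merged across genome pairs by
single linkage; an inconsistent RBH triangle is split into singletons. A
shared 4-mer prescreen keeps the all-vs-all cost linear in practice; it
is disabled in the oracle tests. The e-value-like statistic is the
Karlin–Altschul form `K m n exp(-lambda S)` with ungapped BLOSUM62
constants — a ranking and filtering device, not a BLAST replica.

Because gene order is strictly conserved in the genomes this package
targets, the default `hybrid` mode then interpolates by synteny: anchor
families (present in every genome) delimit intervals, and the remaining
loci of each genome inside an interval — singletons and members of
partial families — are zipped in gene order when every genome with
leftovers has the same number of them. Each zipped row must pass a
homology check against the row's best-supported member; this is what
prevents two *complementary* losses in the same interval from being fused
into a chimeric family, while still folding badly frameshifted genes
(whose garbled proteins fail RBH) into their true families.

# Dollo polarization

Gains are forbidden: a family non-absent in any leaf was present in the
root. Severity may only increase along each root-to-leaf path
(INTACT → PSEUDOGENE → ABSENT; slippage frameshifts count as intact and
are carried as branch annotations, not Dollo states, since they are
potentially revertible). Among assignments of severities to internal
nodes, the reconstruction minimizes the number of state-changing edges
and breaks ties toward the lowest internal severities, i.e. events are
placed as late (leafward) as possible. The search is exhaustive over
internal-node assignments, which is exact and instantaneous for the
three-leaf trees this analysis targets (guarded at 10 internal nodes).
Per-lineage "missing or eroded" counts attribute an event to every leaf
below its branch, so a stem event counts for both descendant lineages.

Slippage frameshifts observed at the same reference-aligned position
(within 10 bp — the indel position inside a homopolymer tract is only
defined up to the tract) with the same sign in several genomes are
treated as a single inherited event and placed on the stem of the clade
formed by those genomes, the dnaX-type case.

# Replication origin, hotspots, palindromes

GC skew `(G-C)/(G+C)` is computed in sliding windows (defaults 1000 bp /
10 bp); zero-GC windows are recorded as 0 and flagged rather than
dropped, keeping the profile aligned to positions. The cumulative skew is
detrended (the total drift is subtracted) before its extrema are read:
the minimum marks the origin and the maximum the terminus when the
leading strand is G-rich, and the symmetric construction makes the call
orientation-free. A call is confident only when the mean-skew contrast
between the two replichores clears both an absolute floor (default 0.01)
and four standard errors estimated from non-overlapping windows; uniform
sequence therefore yields "no confident origin".

The deletion hotspot scan formalizes a qualitative observation: windows
(default 32 kb, the extent of the origin-adjacent cluster in the
motivating data) anchored at each missing-gene position are scored by
count, and the null re-places the same number of positions uniformly on
the circle, recording the *maximum* window count per replicate — the
permutation p-value is thus corrected for scanning. Windows with
`p < alpha` are merged and flagged `near_origin` when within one window
length of the predicted origin. The permutation count defaults to 9,999
and a seed is required.

The palindrome scanner finds EMBOSS-style inverted repeats: arm length
30–1000 bp, gap at most 20 bp, at most 3 substitutions between the second
arm and the reverse complement of the first. "Length" bounds are
interpreted as arm-length bounds and the reported length is the total
span `2*arm + gap`, consistent with spans in the 60–140 bp range reported
for real reduced genomes. Arms are maximal — innermost and outermost
pairs match, no inward or outward extension is possible within the
mismatch budget — and overlapping hits are reduced to a non-redundant set
keeping the longest arm (ties: fewer mismatches, then leftmost). The
inner scan is compiled (Rcpp) because the enumeration of antidiagonal
centers is quadratic-flavored and must run over ~0.7 Mb genomes; a
brute-force R implementation of the same contract serves as the oracle in
the tests. Homopolymer tract counting follows the transcribed strand:
a genomic polyT run inside a minus-strand CDS is a coding-strand polyA
(`strand = "genomic"` is available for the alternative convention).

# Rates

For every family with a usable CDS in all three genomes, the three
pairwise dN values are computed from codon alignments (global protein
alignment back-translated to codons; gapped, ambiguous and stop columns
dropped pairwise) with Nei–Gojobori (1986) counting and the Jukes–Cantor
correction `dN = -(3/4) log(1 - (4/3) pN)`. Conventions: substitutions to
stop codons count as nonsynonymous in the per-site fractions; mutational
pathways passing through a stop get zero weight (with an equal-weight
fallback if every path is blocked); `pN >= 3/4` is reported as saturated.
This deterministic counting estimator replaces codon-model maximum
likelihood deliberately: it is self-contained, exactly testable against a
per-codon pathway enumeration oracle, and adequate for *ratios* of
branch-specific rates at the divergences involved (roughly 0.1–0.2
substitutions per site).

The three-point decomposition `K1 = (d12 + d13 - d23)/2`,
`K2 = (d12 + d23 - d13)/2` (taxon 3 the outgroup) gives the per-gene
fold-increase `K1/K2`. Negative solutions — expected sampling noise at
low divergence — are clipped to zero and flagged, and the fold is
reported as undefined for clipped or saturated genes; a clipped numerator
would otherwise report an artifactual fold of exactly 0. Genes whose only
defect is a single slippage indel are corrected (the indel removed or the
tract base re-duplicated) and treated as intact, so frameshifted genes
contribute rate information.

# The simulator and what passing tests mean

`simulate_triad()` builds a circular ancestor of `n_genes` stop-free CDS
(ATG start, TAA/TAG stop) with geometric spacers and evolves it along a
rooted three-leaf tree. Defaults are the study conditions for a reduced
ant-endosymbiont triad: 600 genes of ~1 kb, 27.5% GC, geometric spacers
whose median sits near 134 bp (mean 193 bp), leaf branches of 0.05
substitutions/site over a 0.03 stem with a 0.10 outgroup, ten intergenic
palindromes (arms 32–58 bp, gaps 0–20 bp, spans 64–136 bp), and a GC-skew
amplitude of 0.08 switching sign at the origin and its antipode. Event
rates are per branch, reproducing the strongly asymmetric per-lineage
reduction of the motivating system — roughly 30 genes missing or eroded
along the first lineage (including eight extra deletions planted in a
32 kb window centred on the origin), high twenties along its sister, and
a handful along the outgroup lineage despite its longer branch — plus
about eight slippage frameshifts in the first lineage and four in each of
the others, one of them typically inherited from the sister-pair stem
(the dnaX-type case). Scalar rates applied uniformly to every branch
remain available.

Design choices that matter for interpretation:

* Substitutions follow a discretized F81 model at the AT-biased
  equilibrium: a site with base `a` changes with probability
  `(1 - pi_a)(1 - exp(-beta t))`, `beta = 1/(1 - sum(pi^2))`, and the
  replacement is drawn from the equilibrium restricted to the other
  bases. This keeps base composition stationary (a naive
  equal-opportunity kernel drifts GC upward by about a point per 0.1
  substitutions/site) and makes the expected number of changes per site
  equal to the branch length. A replacement creating an internal stop
  codon is re-drawn among the remaining bases, so "intact" genes never
  acquire chance nonsense codons. No rate heterogeneity is modeled.
* Stop-codon rejection during ancestor construction would pull realized
  GC about one point above target (stop codons are AT-rich words), so the
  per-codon sampling GC is calibrated by root finding to hit the target
  exactly.
* Planted features that the pipeline must recover — slippage tracts (with
  one flanking base), pseudogene disruptions, palindromes — are protected
  from subsequent substitution. Biologically this stands in for
  stabilizing selection (conserved palindromes) or for the short time
  scales involved; operationally it guarantees every manifest event is
  detectable in principle. For the same reason an event is skipped when
  it would leave a family without a single pristine leaf copy (with no
  intact reference anywhere, no comparative method could classify the
  family), or when it would make the affected leaves exactly a clade
  larger than the event's own branch: independent losses on two sister
  leaves are indistinguishable from a single stem loss under Dollo
  parsimony, so such configurations are never planted. Convergent events
  on non-sister branches - the identifiable kind, and the kind observed
  in real reduced genomes - remain.
* Pseudogenization always plants at least one premature stop (plus up to
  two small indels), so it can never be confused with the
  single-tract-indel slippage rule. Pseudogenized elements stop evolving
  afterwards — a simplification (real pseudogenes evolve faster) that
  only removes further, redundant evidence of disruption.
* Deletions leave a scar spacer retaining a Uniform(0, 0.3) fraction of
  the gene, below the 0.6 presence-screen coverage, so spacers spanning
  missing genes are measurably long but never re-called as present.
* Slipped genes are stored frame-corrected, with the indel materialized
  at assembly; descendant substitutions therefore respect the functional
  reading frame, which is what makes the inherited (stem) frameshift case
  reproducible.

What passing tests therefore show: the pipeline recovers exactly this
kind of signal — conserved gene order, moderate divergence, point
substitutions plus the planted event types — with event-level precision
and recall of 1.0 at the default divergences. What they do not show:
robustness to rearrangements, paralogy, annotation error, rate
heterogeneity, within-gene recombination, or indel evolution outside the
planted events; none of these are modeled, and real-data counts that
depend on curation decisions should be read as benchmarks with tolerance,
not as exactly reproducible numbers.

# Problem sizes and determinism

The test suite runs the full analysis on triads of 60–120 genes and the
rate recovery on 200 genes x 300 codons; the acceptance script runs the
study conditions (600 genes, ~700 kb genomes) plus the two rate
simulations. Every stochastic component takes an explicit seed — the
simulator configuration requires one, and the hotspot permutation null
accepts one — so all reported numbers regenerate exactly.

# A worked example

```{r example, eval = FALSE}
library(reducta)

cfg <- sim_config(seed = 42, n_genes = 120, hotspot_losses = 4,
                  hotspot_width = 20000)
sim <- simulate_triad(cfg)
res <- analyze_reduction(sim$genomes, cfg$tree, n_perm = 999, seed = 7)
res
#> <reduction_analysis> 3 genomes, 120 families
#>   ancestral genes: 120 | intact in all: 107
#>   vafer: 7 missing/eroded, 3 frameshifted
#>   floridanus: 4 missing/eroded, 0 frameshifted
#>   pennsylvanicus: 2 missing/eroded, 1 frameshifted
#>   convergent families:
#>   origin (vafer): 91690 between vafer_0073 and vafer_0074
autoplot(res$skew_profile, res$origin)
plot_lineage_events(res)
```

# Known limitations

* Orthology assumes (near-)paralog-free, synteny-conserved genomes; it is
  not a general orthology inference tool.
* The origin caller reads compositional skew only; it does not model
  replichore asymmetry beyond GC skew, and weakly skewed genomes are
  reported as "no confident origin" rather than guessed.
* dN uses equal-weight NG86 counting; absolute values at high divergence
  will differ from codon-ML estimates even though fold-ratios are stable.
* The exact rank-sum enumeration is limited to pooled samples of 20
  (runtime); beyond that a tie- and continuity-corrected normal
  approximation is used.
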