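---
title: "Synteny blocks, paleopolyploidy and silent-site clocks: methods and design"
author: "paleosyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synteny blocks, paleopolyploidy and silent-site clocks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A BAC-based physical map gives an ordered set of exonic markers along each
chromosome of a query genome, with physical positions in Kb along the
minimum tiling path (MTP) and, for a subset, genetic positions in cM.
Comparing that marker order against the annotated pseudomolecules of
sequenced subject genomes answers three questions at once:

* **how much collinearity survives** between the two genomes (synteny and
  its erosion over divergence time),
* **whether either lineage underwent a whole-genome duplication (WGD)** —
  a WGD in the *subject* shows up as parallel synteny tracks over one
  query chromosome, a WGD in the *query* as the same subject interval
  syntenic with two different query chromosomes — and which query
  chromosomes are ancient homoeologues, and
* **where the centromeres sit**, because pericentromeric regions are both
  devoid of exonic-marker synteny and recombinationally silent.

On top of the block structure, coding-sequence alignments of syntelog
pairs (duplicates retained at collinear positions since the WGD) date the
duplication through the synonymous distance `Ks` and the molecular-clock
relation `r = Ks / (2 t)`.

`paleosyn` implements this entire chain as testable code, together with a
genome-evolution simulator that generates every input with known ground
truth, so each stage can be validated quantitatively rather than by
inspection.

# Collinear chains and synteny blocks

Markers are joined to their best and second-best homologous gene per
subject genome (lowest BLAST e-value; ties by bitscore, then gene id;
the second slot must be a *different* gene, so multiple HSPs on one gene
never occupy both). Both hits enter chaining as separate anchor points,
which is what lets a duplicated subject region appear as its own parallel
track and makes the best/second alternation test possible.

Within one (query chromosome, subject chromosome) pair, a chain is a
maximal run of anchor points whose subject gene starts move strictly
monotonely along the query, under three tolerances:

* `jitterKb` (default 200): marker order is only known to one BAC length,
  so an order violation between points closer than this on the query is
  forgiven;
* `maxDiscordant` (default 2): up to this many consecutive non-fitting
  points may be skipped (they are flagged non-collinear). The skip budget
  counts *all* points of the subset, including points already claimed by
  a previously extracted chain — without that, leftover discordant points
  chain with one another across whole chromosomes once the dense primary
  chain has been removed, and the collinear fraction becomes a near-100%
  artifact;
* `maxAnchorGapKb` (default 2000): consecutive chain members further
  apart than this on the query terminate the chain. An optional
  `maxSubjectGapKb` applies the same bound on the subject axis; it is off
  (`Inf`) by default because collinearity as such puts no limit on
  subject spacing.

The chain search is an exact dynamic program (the skip bound makes it
linear-time); chains are extracted longest-first so same-subject-chromosome
parallel tracks separate into successive chains. An exhaustive
depth-first reference search (`bruteForceChainLength`) implements the same
semantics independently and the test suite checks the two agree on random
anchor tables.

A chain survives as a **synteny block** when it contains at least
`minGenes = 3` distinct subject genes and spans at least
`minSpanKb = 500` (about 0.5 Mb) of query MTP. Blocks on one query
chromosome whose spans overlap by at least half of the shorter span form
a parallel group (transitive closure); within a group blocks rank
primary/secondary/tertiary by descending query span. The headline
statistics are the summed block lengths by rank (`ΣSB_1`, `ΣSB_2`,
`ΣSB_3`, in Mb of query MTP, and as percent of the total map) and the
secondary-to-primary length ratio **S/P = ΣSB_2/ΣSB_1**, the syntenic
depth signal used to call WGDs. The percent-collinear denominator is the
number of markers with at least one passing hit in that comparison.

# WGD detection and homoeologues

`wgdCall(spTest, spBenchmark)` is positive when the test comparison's S/P
ratio exceeds a benchmark comparison's — one against a genome whose only
duplication predates the split — by more than `marginFrac = 0.5`
(i.e. 1.5x). The benchmark absorbs whatever parallel-track depth the
shared ancestral duplication contributes, so only a lineage-specific WGD
trips the call.

Query-side WGDs are found from **duplicated block pairs**: blocks on
*different* query chromosomes whose spans on the same subject chromosome
overlap by at least half of the shorter span, *or* by at least 3 Mb
absolute. The absolute branch is needed because chained blocks can run
tens of Mb: two genuinely homoeologous long blocks offset by half a span
share a huge overlap yet fail any purely fractional test.

The homoeology matrix counts, for each ordered chromosome pair (c1, c2),
the collinear markers of c1 lying in a duplicated portion supported on
c2. Support is local: the marker's gene must fall inside the pair's
subject-span overlap *and* the partner block must hold an anchor within
`supportWindowKb = 500` of it. Without the local condition a sparse
remnant chain stretched across a dense block claims the dense block's
entire marker count and partner assignment fails. Partners are row-percent
maxima (percentages neutralise chromosome-size differences); a pair is
reciprocal when each member is the other's partner. The same
local-support rule defines the duplicated fraction of collinear markers;
counting whole-block pair membership instead saturates near 100% for long
blocks. Ancestral chromosome composition merges the ordered
subject-chromosome labels of a homoeologue pair (order from the member
with the larger block span, insertions from the other at their flanking
positions, longest-common-subsequence matching); a block present in one
member and absent genome-wide is tagged single-copy — the signature of a
post-WGD deletion.

# Recombination profiles and centromeres

Anchors are the nearest genetically mapped markers to every 5 Mb grid
point (ties to the smaller position; chromosomes shorter than two steps
are flagged too short). Interval rates Δ cM / Δ Mb (clamped at zero)
are smoothed by averaging the two intervals flanking each anchor; at the
chromosome ends only a single flanking interval exists, so the pass is
run in both directions and the two estimates averaged. The global
minimum (ties resolved to the centroid of the tied windows) and the
strict local maxima (terminal windows count against their single
neighbour) summarise each profile. A **centromere call** is made where
the global-minimum window (centre ± step/2) overlaps a synteny gap — a
maximal interval of at least 1 Mb overlapped by no block — shared by all
supplied genome comparisons; if minimum and gap do not coincide, both
candidates are reported and no call is made. "Within one window" in the
validation suite means the called minimum centre lies within 7.5 Mb
(one step plus half a window) of the true centromere midpoint.

# The Nei–Gojobori clock

`ng86Ks` counts synonymous sites per codon as the per-position fraction
of the three possible changes that preserve the amino acid (changes to
stop codons count as nonsynonymous), averaged over the two sequences.
Codons differing at d positions are resolved over all d! single-step
paths; paths through stop codons are excluded (if every path is blocked,
all paths are used). The Jukes–Cantor correction
`K = -3/4 ln(1 - 4p/3)` accounts for multiple substitutions per site;
`p >= 3/4` flags saturation, and the uncorrected proportions are
available with `variant = "pdistance"`. Codon columns containing gaps or
ambiguity codes are dropped pairwise. The implementation is checked to
1e-10 against an independently written enumeration oracle.

Outlier removal before averaging Ks is leave-one-out: the largest value
is removed while it exceeds the mean plus 3 SD of the *remaining* values.
A plain full-sample mean + 3 SD cut cannot remove a gross outlier from a
small set — the outlier inflates the SD past its own value — which is why
the leave-one-out form is the default (a Tukey Q3 + 3 IQR rule is
selectable). The rate follows as `r = Ks/(2t)` with `t` the divergence
time in years, and cross-lineage comparisons as fold ratios.

# The simulator: what it emulates

`evolutionScenario()` fixes the study conditions; the defaults are the
walnut-style design:

* an x = 8 ancestor built as the fractionated remnant of an **ancestral
  (pre-split) duplication** at 130 MYA: four proto-chromosomes are
  duplicated and retained in clustered runs (mean 25 genes retained in
  duplicate at stationary fraction 0.10, the rest kept on one member).
  Every lineage inherits this baseline duplication state, which is what
  gives the benchmark comparison its non-zero S/P ratio. Modelling the
  baseline as a *post-split* WGD instead would make the two subject
  copies equidistant co-orthologues of every marker and drive the
  benchmark S/P toward 1 — the configuration cannot reproduce a
  grape-like low baseline, which is why the duplication lives in the
  ancestor;
* one gene per 40 Kb, ~2,150 genes per post-duplication ancestral
  chromosome, so the query genome lands near 736 Mb and ~11,500 markers
  after the query WGD (60 MYA) and fractionation;
* duplicate-biased fractionation at 0.01 per duplicated gene per MY
  (copies of lineage-WGD duplicates only; ancestral duplicate pairs that
  survived to the ancestor are treated as retained for good), background
  loss 0.002, transposition 1e-4 per gene per MY, inversions 0.5 and
  reciprocal (arm-exchange, centromere-preserving) translocations 0.005
  per genome per MY. The translocation rate is deliberately low: the
  observed homoeologue structure keeps the same blocks in the same order
  after 60 MY, i.e. essentially no fixed interchromosomal exchange;
* **clustered homology opacity**: runs (mean 80 genes) of query genes
  with no detectable subject homologue, at fraction
  `1 - exp(-divergence/600 MY)`. This is the mechanism that erodes
  synteny *coverage* with divergence time — single-gene losses cannot,
  because physical positions are laid out per surviving gene and leave
  no query-side hole;
* markers sampled at 20 per Mb outside a ±5 Mb pericentromeric zone
  (exonic BAC-end markers are absent from repeat-rich centromeres, which
  is how the centromere manifests as a shared synteny gap), physical
  positions jittered within ±200 Kb (one BAC length), 10% of markers
  genetically mapped with cM from a centromere-suppressed intensity
  profile (2.5 cM/Mb distal, 0.63 pericentromeric, 5 Mb ramps; the
  extremes follow the recombination regime reported for such maps);
* homology hits with rank-consistent scores: orthologues (same
  ancestral-duplication copy) score by the split-path divergence,
  ancient paralogues by the duplication-age path, so orthologues outrank
  paralogues on average but not always; 2% of markers get a spurious
  near-threshold hit;
* syntelog coding sequences built from codons with fourfold-degenerate
  third positions, evolved along both post-WGD branches under
  Jukes–Cantor dynamics at `rTrue = 2.29e-9` substitutions per silent
  site per year, so the expected pairwise Ks is `2 t rTrue`.

The `benchmark` subject (110 MY branch) carries no lineage WGD; the
`test` subject (105 MY) carries one at 65 MYA. One scenario seed
determines every output exactly.

**What the simulator does not emulate:** real BES homology noise (tandem
arrays, gene families, partial exons), TE content, base-composition
bias, selection, biased subgenome fractionation, and genuinely
three-copy ancestral states (a triplication would have to be approximated
by nested duplications). Consequently the simulated collinear fractions
are far higher than the ~14–35% of real BES data, and passing the
validation suite demonstrates correctness of the *method* under the
modelled mechanisms, not that real data would reach the same accuracy.

# Group statistics

Per-chromosome values of each measure are compared across genome
comparisons by one-way fixed-effects ANOVA with unprotected Fisher LSD at
α = 0.05; proportions are arcsine-square-root transformed first, absolute
lengths are analysed untransformed. The compact letter display uses the
insert-and-absorb algorithm and is tested to encode exactly the pairwise
LSD decision matrix. Marker segregation is screened with the 1-df
chi-square against 1:1 at P = 0.01, without continuity correction.
Genetic-map gaps above a threshold (with optional rescaling of a
comparison map) are totalled and expressed as percent of map length.

# Numerical and design choices

* Gene models are held as `GRanges` (1-based, closed — the Bioconductor
  convention); `rtracklayer` performs GFF3/BED conversions, so the
  half-open/closed bookkeeping never appears in package code. The
  0-based starts written into anchor tables are used for ordering only.
* "About 0.5 Mb or more" is enforced as a strict `>= 500` Kb; "at least
  three different collinear genes" counts distinct subject gene ids.
* Degenerate inputs: an empty anchor table yields an empty chain set;
  zero primary length yields S/P = 0; no collinear markers yields an NA
  duplicated fraction; a benchmark S/P of zero is a validation error for
  `wgdCall`; chromosomes shorter than two window steps are excluded from
  recombination profiling.
* Rank ties in parallel groups break to the smaller subject chromosome
  label; anchor-grid ties to the smaller physical position; profile
  minima ties to the centroid of the tied windows.
* Validation problem sizes: the acceptance script runs 20 replicate
  scenarios for the WGD caller, 3 replicate scenarios (48 chromosomes)
  for homoeologue and centromere recovery so a single anomalous
  chromosome cannot flip a 90% criterion, 1,000 random codon pairs for
  the NG86 oracle, 100 syntelog pairs for clock recovery, a five-point
  divergence grid for erosion monotonicity, and 200 random anchor tables
  for the chain oracle.

# Limitations

Chained blocks are maximal and can therefore run much longer than
hand-curated synteny blocks; all downstream rules that the literature
states in per-block terms (overlap fractions, pair membership) are
implemented with the absolute-overlap and local-support refinements
described above, and would need re-examination for data with radically
different marker densities. Homoeologue pairing assumes duplicated
content remains concentrated on one partner chromosome; heavy segmental
deletion (a shrunken homoeologue) is detected only as loss of
reciprocity, not adjudicated. The clock stage consumes externally
aligned coding sequences; alignment itself is out of scope.
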