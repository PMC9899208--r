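---
title: "Methods: duplication scanning, GRINS calling and module phylogeny"
author: "grinscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: duplication scanning, GRINS calling and module phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grinscan)
```

## The problem

Modular polyketide synthases (PKSs) are giant bacterial enzymes organized
as assembly lines of modules, each minimally a KS–AT–ACP domain set with
optional KR, DH and ER processing domains. Pairs of modules within one
cluster are often not independent inventions but products of intra-cluster
gene duplication and subsequent gene conversion. Two sequence-level
footprints betray this history:

1. **Duplicated regions** — stretches of the cluster DNA with high
   identity to another, non-overlapping stretch of the same cluster.
2. **GRINS** (genetic repeats of intense nucleotide skews) — duplicated
   regions whose base composition is strongly biased on both the G/C and
   T/A axes. Their biased, low-complexity composition is thought to make
   them preferred substrates for gene conversion, which can recode a
   neighboring homologous module.

`grinscan` detects both footprints in a cluster nucleotide sequence and,
independently, reconstructs the evolutionary relationships among module or
domain sequences with a distance phylogeny, so that a claim like "modules
3 and 6 derive from a recent duplication" can be supported by (a) an
identity matrix, (b) a GRINS track, and (c) a sister-pair relationship in
the tree.

## Duplication scan

The cluster is cut into overlapping windows of `win_len` = 150 bp advanced
in steps of 30 bp; only full-length windows are kept, so a cluster of `L`
bp yields `floor((L - 150)/30) + 1` windows. Every window is globally
aligned against every *eligible* partner window — eligibility means the
two genomic intervals do not overlap, plus an optional `min_separation`
margin — and the highest percent identity is kept per window
(`max_identity_profile()`).

Identity is defined as identical aligned columns divided by alignment
length, gap columns included in the denominator. Alignment is end-to-end
with affine gaps, scored match +5, mismatch −4, gap open −10, gap extend
−0.5 (the ubiquitous EDNAFULL-style DNA parameters). Under this scoring a
pair differing only by substitutions at the rates relevant for duplication
detection almost always aligns gap-free, so the identity then equals the
Hamming-based value `100 (1 − mismatches/150)`; the tests condition the
Hamming-oracle comparison on gap-free optimality because a local repeat
occasionally lets a gapped alignment outscore the gap-free one even at
10% divergence. `N` bases never count as matches, and windows that are
more than half `N` are excluded from partnering entirely, so masked
sequence cannot seed calls.

Duplicated regions are then called (`call_duplicated_regions()`) as
maximal runs of windows whose *centered 5-window sliding mean* of best
identity strictly exceeds 80%, the run's window intervals are unioned, and
regions spanning < 500 bp are dropped. Three numerical details:

* at the profile edges the sliding mean is truncated to the available
  neighbors rather than discarding terminal windows;
* because windows overlap (150 bp at step 30), two marked runs separated
  by a short unmarked gap can still overlap in base space; such regions
  are merged (window-count-weighted mean identity) so reported regions are
  always disjoint;
* ties in best-partner choice go to the lowest window index, making the
  profile deterministic.

Two performance modes exist and are validated against each other in the
test suite: the default applies a shared 12-mer prefilter before aligning
a pair (a pair of 150-mers above the 80% threshold shares long exact
stretches with near-certainty), and `exhaustive = TRUE` aligns every
eligible pair. `fast = TRUE` replaces gapped alignment with exact ungapped
identity, appropriate when duplications are substitution-dominated.

The eligibility default (`min_separation = 0`, i.e. any non-overlapping
partner) follows the definition of the scan literally. Note that adjacent
windows share 120 bp of sequence; they are excluded only because their
*intervals* overlap. For real clusters with tandem micro-repeats a
`min_separation` of one window length is a reasonable stricter setting and
is exposed as a parameter.

## Skews and GRINS calls

Per window on the same grid, `gc_skew` = (G−C)/(G+C) and `ta_skew` =
(T−A)/(T+A); a window with a zero denominator carries an undefined (`NA`)
skew rather than an imputed zero, since imputation would bias regions
toward failing. A duplicated region is promoted to a GRINS call
(`call_grins()`) when the mean of the *absolute per-window* skews over its
member windows exceeds `skew_min` = 0.15 **for both skews**. Averaging
|skew| per window rather than pooling counts over the whole region is
deliberate: a region whose skew alternates in sign is intensely skewed
locally yet would pool to zero. The conjunctive ("both") reading of the
threshold is the default because GRINS are defined by bias on both axes;
an `"either"` rule is available for sensitivity analysis. Raising
`skew_min` can only demote calls (monotonicity, tested), and every GRINS
call is exactly one of the input duplicated regions — GRINS form a subset
of the duplication track.

## Module and domain phylogeny

Distances are computed per pair of coding sequences. Each pair is aligned
codon-aware (`codon_align_pair()`): the translated proteins are globally
aligned under BLOSUM62 with gap open −11 / extend −1, and each amino-acid
column is expanded back to its source codon, so nucleotide gaps always
have length divisible by 3 and the reading frame survives. The raw
mismatch proportion `p` over comparable sites (columns with no gap and no
`N` in either row — pairwise deletion) is corrected with the Jukes–Cantor
model, `d = −(3/4) ln(1 − 4p/3)`, and the tree is built by canonical
Saitou–Nei neighbor-joining with lowest-index tie-breaking and negative
branch lengths clamped to zero. On an additive matrix the implementation
reproduces the generating tree exactly (tested on random trees, and
cross-checked against the independent `ape::nj`).

A deliberate divergence from the typical toolchain: the reference
procedure for such analyses aligns all modules jointly (MUSCLE in codon
mode) and feeds the MSA to a distance method. Because the tree is built
from *pairwise* distances, a joint MSA is unnecessary — pairwise
codon-aware alignments give the same quantity per pair, keep the
computation self-contained, and make every pair independently testable. A
pre-aligned set can still be supplied (`aligned = TRUE`), in which case
pairs are sliced from the given columns.

At `p ≥ 0.75` the Jukes–Cantor correction is undefined (saturation);
the affected pair is reported by name and the run aborts unless
`cap = TRUE` replaces the distance with 5.0 substitutions/site. Capping is
off by default because a saturated pair usually signals a non-homologous
comparison rather than a measurable distance.

Topology queries answer the two questions this analysis asks of a tree:
`is_sister_pair()` (do two leaves form a cherry of the unrooted tree —
e.g. the duplicated modules) and `split_consistent()` (does a single edge
separate two leaf classes exactly — e.g. malonyl-specific ATa modules
from methylmalonyl-specific ATp modules). Trees are left unrooted; NJ
produces no root and rooting is presentational.

## Homology report

`identity_matrix()` computes all-vs-all pairwise global identities between
annotated regions at the nucleotide or protein level (same scoring as the
scan / BLOSUM62 respectively); the identity denominator is the full
alignment length including gap columns, the most conservative common
convention, and is the convention for every identity this package reports.
`top_homolog_pairs()` ranks the off-diagonal entries. `flag_truncated()`
flags domains whose amino-acid length falls at least `delta_min` = 40
residues short of their class median; the median is used rather than the
mean so the truncated members themselves cannot drag the reference down,
and 40 gives margin below the ~50-residue truncation that motivates the
flag while staying above ordinary length variation.

## The synthetic generator

Real deposited PKS clusters are external inputs; the generator provides
clusters with *known* truth so every stage is testable. Defaults model a
streptomycete cis-AT PKS at desk scale: 8 modules × 900 bp (300 codons)
separated by 150-bp spacers at 72% GC. Modules are random sense codons
(stop-free, independent-base codon probabilities at the target GC,
renormalized after removing the three stop codons); spacers are i.i.d.
bases.

* `plant_duplication()` copies an interval and substitutes each site with
  probability `sub_rate`, always to a different base, so expected identity
  is exactly `100 (1 − sub_rate)` — clean targets for scan tests.
* `plant_skew()` resequences an interval i.i.d. with base probabilities
  solving the two skew equations at the configured GC; ORF structure
  inside the interval is sacrificed, which is acceptable because GRINS
  detection reads raw nucleotides. Boundary targets (|skew| = 1) are
  rejected as they require a zero base probability. On a 900-bp interval
  the realized window-mean |skew| fluctuates around its target with sd
  ≈ 0.04 (only ~6 non-overlapping windows fit), which is why calibration
  tests average over replicate plantings.
* `evolve_on_tree()` runs a per-site Jukes–Cantor process along a given
  tree (substitution probability `(3/4)(1 − e^{−4d/3})` per branch), the
  model the distance pipeline assumes — so tree-recovery tests are
  internally consistent. Unlike `plant_duplication`, back-substitutions
  occur, matching the JC expectation rather than an exact identity target.

Every generator operation is a pure function of its inputs and an explicit
seed; nothing touches the global random stream.

What the generator does **not** emulate: indels, recombination or gene
conversion as a stochastic process, realistic domain grammar within
modules, codon-usage bias beyond the GC target, and intergenic regulatory
structure. Passing tests therefore demonstrate correctness of the
*detection machinery* under the stated models, not performance on real
clusters, where identity denominators, conversion mosaics and annotation
uncertainty add noise on the order of a percentage point or two.

## Flagship fixture and problem sizes

The repository's central integration fixture is a ~10-kb, 10-module
cluster in which module 3 receives skew targets (0.3, 0.3) and is then
tandem-duplicated at 5% divergence, while module 8 is tandem-duplicated
without skew. The pipeline must report the duplication track over both
loci and exactly one passing GRINS call, on the skewed locus — the
two-duplicate contrast separates "duplicated" from "duplicated + skewed".
Tandem placement mirrors the biological arrangement of GRINS repeats and
keeps each planted locus a single called region (at higher divergence the
junction window can dip below the threshold and split a locus into two
abutting calls; the union of calls remains the stable quantity).

Test and acceptance problem sizes — 10-kb clusters, 900-bp modules,
1,500-site tree simulations with 10 replicates, 200 random trees of 4–12
leaves for the NJ exactness property — were chosen so the whole suite
exercises every code path in about a minute on a laptop while all
binomial-concentration bounds in the tests have comfortable margins.

## Known limitations

* The quadratic all-vs-all scan with the k-mer prefilter handles tens of
  kilobases comfortably; for 100-kb-scale clusters use `fast = TRUE` or a
  larger `step`.
* Identity conventions differ between tools (denominator, gap treatment);
  reported identities can differ by ±1–2 points from other pipelines on
  the same input, so thresholds should be interpreted with that margin.
* Reverse-complement (inverted-repeat) duplications are detected only when
  `revcomp = TRUE` and are off by default.
* Module/domain boundaries are always user-supplied; no HMM-based domain
  annotation is attempted.
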