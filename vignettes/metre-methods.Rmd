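---
title: "Scoring barcode markers with the Mean Taxonomic Resolution index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring barcode markers with the Mean Taxonomic Resolution index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metre)
```

## The problem

DNA barcoding delimits species by comparing the distance between a query
sequence and reference sequences against the variability observed within
species. For fungi the classical markers are the multicopy rRNA regions
ITS and LSU, with community-accepted identity thresholds (1.4% and 1.0%
respectively); single-copy protein-coding genes (ACT1, TEF1-alpha, RPB1,
RPB2) are increasingly attractive because they can be harvested directly
from genome assemblies and avoid paralogy within the rRNA arrays. Judging
whether a marker *actually separates* a given set of species requires
putting inter- and intraspecific distances on a common scale.

`metre` implements that comparison as a pipeline: capture a marker locus
from assemblies with a probe sequence, align the captured and reference
sequences, compute raw p-distances and within/between-species means, and
condense each species pair into a single dimensionless number, the Mean
Taxonomic Resolution (MeTRe).

## The index

For species $i$ and $j$, let $D_{i-j}$ be the arithmetic mean of all
pairwise p-distances between their strains, and $D_i$, $D_j$ the
arithmetic means of all within-species pairwise distances. The
actual-variability form is

$$\mathrm{MeTRe}_{i-j} = \frac{D_{i-j}}{D_i + D_j},$$

and the fixed-threshold form substitutes the denominator with a marker
threshold $Th$ equal to two half-thresholds (0.014 for ITS, 0.010 for
LSU):

$$\mathrm{MeTRe}_{i-j} = \frac{D_{i-j}}{Th}.$$

A MeTRe matrix has a diagonal of exactly 1 by convention (a species'
variability divided by itself); a pair is *resolved* when its MeTRe is
strictly greater than 1 and unresolved at $\le 1$ — the boundary case is
deliberately classified as unresolved, because at MeTRe $= 1$ a strain at
the species border is equally distant from both type strains. The index
is dimensionless and scale invariant in its first form (multiplying all
distances by a constant changes nothing), while the threshold form scales
linearly with distance.

Interpretation guidance: the first form measures the *actual* separation
of the strains at hand and is the only option for markers without an
accepted threshold; the threshold form anchors the comparison to the
community convention and is most useful for ITS and LSU. Degenerate cases
are kept explicit rather than absorbed: zero internal variability with
positive separation gives an infinite MeTRe (excluded from means, counted
separately), 0/0 is undefined, and singleton species have an *undefined*
within-mean — a fallback (e.g. $Th/2$) can be supplied explicitly but is
never imputed silently.

## Capturing markers from assemblies

A marker is located in an assembly by exact-match anchoring, the
semantics of aligner-based workflows that feed coordinate tables into
`faidx`-style extraction:

1. **Anchors** — every maximal exact match of length at least
   `min_match_len` (default 20 nt) between the probe, in either
   orientation, and any contig is reported, regardless of uniqueness.
   Matches never cross non-ACGT characters: an `N` in the assembly breaks
   an anchor, and IUPAC ambiguity codes never match anything.
2. **Chaining** — per contig and strand, anchors are clustered (a new
   cluster opens when the genomic gap between consecutive anchors exceeds
   the probe length) and each cluster is reduced to its best colinear
   chain: the subset, strictly ordered and non-overlapping in both
   genome and probe coordinates, maximizing total matched bases.
   Coverage is matched bases over probe length.
3. **Filtering and extraction** — chains with coverage below
   `min_coverage` (default 0.5) are dropped; chains whose genomic
   bounding boxes overlap by more than half of the shorter region are
   merged, keeping the higher-coverage one (ties: longer region, then
   contig name, then smaller start). Each surviving region `S1..E1`
   (1-based, inclusive at both ends) is extracted and, for reverse-strand
   hits, reverse-complemented so that all captured sequences share the
   probe's orientation — mixed orientations entering one multiple
   alignment cannot be meaningful.

Several disjoint passing loci in one genome are all returned with ids
`genome.1`, `genome.2`, ... — this is the multi-copy / hybrid-genome
case (e.g. allopolyploid lager yeasts carrying two diverged copies of
nominally single-copy genes), handled generically as multiple hits.

Parameter rationale. `min_match_len = 20` is the conventional anchor
seed length of MUM-based aligners; shorter seeds admit chance hits
(a specific 20-mer occurs by chance once per ~$10^{12}$ bases).
`min_coverage = 0.5` rejects spurious single-anchor chains while keeping
orthologs several percent diverged from the probe: at ~2% divergence the
expected anchored fraction of a locus is still roughly
$(1-p)^{19} \approx 0.68$. Both are exposed, not hard-coded. The
clustering rule (split at gaps larger than the probe) is our
reconstruction of how multiple coordinate rows per genome collapse into
one extraction interval; it keeps tandem or distant extra copies separate
while tolerating anchor fragmentation inside one locus.

A genome is identified by its file-level label (e.g. the assembly
accession used as the file name), not by contig ids — assemblies are
multi-contig and contig headers carry no strain identity.

## Alignment

The builtin aligner is a progressive, ClustalW-style aligner, not a
reimplementation of ClustalW: guide distances are fractional shared
6-mers, the guide tree is neighbor-joining, and profiles are merged by
global affine-gap dynamic programming (Gotoh) in compiled code. Scoring
is identity-based — match 1, mismatch 0 — with transitions (A–G, C–T)
scored `transition_weight = 0.3` during profile merging, so a transition
counts 0.3 where a transversion counts 0. Gap penalties default to
opening 15 and extension 6.66 per base, for both pairwise and multiple
alignment; terminal gaps are penalized like internal ones (a decision —
markers captured full-length should not be rewarded for dangling ends).
Traceback ties prefer the diagonal, then a gap in the second profile,
then a gap in the first, making output deterministic.

Published ClustalW/MEGA alignments differ from ours in internals the
respective defaults never state (weight matrix staging, divergent-
sequence delay), so site-level identity with them is not guaranteed; for
that purpose any external aligner can be substituted via
`engine = "external:<cmd> {in} {out}"` (e.g. MAFFT). Both engines are
held to the same invariant, checked after every run: removing gaps from
any aligned record must reproduce the input residues exactly.

In the substitution-only regime (sequences of equal length differing at
scattered sites) the optimal alignment is the gap-free stacking: any gap
costs at least 21.66 twice while a mismatch costs nothing. The test suite
exploits this to make end-to-end checks equality tests.

## Distances and group means

Distances are raw p-distances: the proportion of compared sites at which
two aligned sequences differ, transitions and transversions counted
alike, no model correction. Two site-deletion policies are first-class,
because published workflows mix tools that default differently:

* `complete_deletion` (default): a site with a gap *or ambiguity code in
  any record* of the alignment is excluded globally;
* `pairwise_deletion`: exclusion is decided per pair.

IUPAC ambiguity codes are treated like gaps — a difference cannot be
established against an ambiguous base, and counting it as a match would
bias distances downward. A pair with zero retained sites is undefined
(`NA`), never 0, and undefined entries propagate as flags rather than
silently dropping to zero. The gap mode used is recorded in the matrix
and in every serialized output. p-distances after site deletion need not
satisfy the triangle inequality; nothing downstream assumes it.

Within-species means average all unordered strain pairs of one species;
between-species means average all cross pairs. Per-strain panels
(distance of every strain of species $a$ to the type strain of species
$b$) are computed relative to type strains, the nomenclatural anchors.
Machine-readable outputs always carry proportions; percentages appear
only in human-facing text, since thresholds are conventionally quoted in
percent.

## Trees and matrix comparison

Neighbor joining delegates to `ape::nj`, the canonical implementation;
negative branch lengths (possible on non-additive input) are clamped to
zero with the difference moved to the adjacent branches, preserving path
lengths through the node where possible. The Mantel test between two
distance matrices uses the Pearson correlation of vectorized upper
triangles with a one-sided permutation p-value,
$p = (1 + \#\{r_{perm} \ge r_{obs}\})/(n_{perm}+1)$, jointly permuting
rows and columns of the second matrix; a seed makes it reproducible, and
an explicit permutation matrix can be injected for exhaustive enumeration
on small label sets. Tree agreement is the Pearson correlation of
cophenetic distance matrices — a quantitative stand-in for visual
tanglegram comparison.

## The synthetic generator

`make_species_set()` builds fixtures whose p-distances are *exact by
construction*, not in expectation. All sequences derive from one random
reference of length $L$; species $i$'s ancestor differs from it at $a_i$
private sites and every strain differs from its ancestor at $p_i$
private sites, with all site sets disjoint:

$$p_i = \frac{w_i L}{2}, \qquad a_i = \frac{b L}{2} - p_i,$$

where $w_i$ is the requested within-species divergence and $b$ the
between-species divergence. Any within-species pair then differs at
exactly $2 p_i$ sites and any cross pair at exactly
$a_i + a_j + p_i + p_j = bL$ sites. This makes acceptance checks equality
tests: the end-to-end pipeline must return MeTRe $= b/(w_i + w_j)$
exactly, and threshold mode $b/Th$. The construction requires $w_i L/2$
and $b L/2$ to be whole numbers and the total edited sites to fit in the
sequence; violations raise errors rather than rounding silently.
Divergences are uniform across species pairs ($b$ scalar); per-pair
heterogeneous targets would need overlapping-site bookkeeping that the
validation goals here never require.

Substitutions are confined to the interior of the locus, leaving
`conserved_flank` (default 30 nt) untouched at each end. Real barcode
loci are flanked by conserved primer-binding regions — that is why they
are amplifiable — and the conserved flanks also guarantee that anchor
chains reach the true locus boundaries, so capture recovers coordinates
and sequence exactly rather than approximately.

What the generator deliberately does *not* emulate: insertions and
deletions (so alignment in the exact regime is trivial by design), rate
heterogeneity among sites, GC bias, intragenomic heterogeneity of rRNA
tandem arrays, assembly fragmentation and sequencing error. Passing the
synthetic suite therefore demonstrates correctness of the computations —
capture coordinates, distances, means, MeTRe arithmetic — not robustness
of any aligner to indel-rich real data. One practical caveat baked into
the tests: background genomes must be drawn from an RNG stream unrelated
to the marker set, otherwise the background can replay the locus's base
stream and create a spurious second copy.

`implant_markers()` places marker copies (forward or reverse-complement)
at chosen positions in a uniform-composition background and returns the
truth table of coordinates, giving the capture stage a fully known
target, including multi-copy scenarios.

## Numerical and policy decisions

* Resolution is strict: MeTRe $\le 1$ (including exactly 1) is
  unresolved.
* Mean MeTRe is the unweighted mean over unordered pairs; per-species
  means use the species' full row minus the diagonal. The two readings of
  a published "average" coincide for symmetric matrices, and both are
  available.
* Infinite and undefined MeTRe values are excluded from means and
  reported as counts, so one degenerate species cannot destroy a summary.
* Captured-marker ids append `.k` suffixes only when a genome yields
  several hits; species lookup strips the suffix, so multi-copy hits
  group with their genome's species.
* All coordinates are 1-based and inclusive at both ends throughout the
  user-facing API; conversions happen only at internal edges.
* Reports are byte-reproducible for a fixed configuration and seed: no
  timestamps in outputs, deterministic orderings everywhere, and the only
  randomized stage (Mantel) is seeded from the configuration.

## Problem sizes

The shipped validation suite runs at desk scale by choice: species sets
of 2–6 species with 2–4 strains, loci of 400–1200 nt, genomes of 5–20 kb,
50 random capture fixtures, exhaustive oracles up to 12 chaining anchors
and 7-base alignment pairs, 200-replicate Mantel calibration at 99
permutations. These sizes exercise every code path (both strands,
multi-copy, boundary MeTRe values, undefined entries) while keeping the
full suite under half a minute; nothing in the implementation is limited
to them — capture cost grows linearly in genome size for fixed anchor
density, and alignment quadratically in locus length.

## Limitations

The builtin aligner targets the substitution-dominated regime typical of
intra-genus barcodes; heavily indel-structured loci should use the
external engine. Exact reproduction of published MeTRe tables for the
*Saccharomyces* and *Candida* panels requires the original assemblies
(the shipped accession manifests list them) and the original aligner;
the package ships the machinery, not the data. Within-group means demand
at least two strains per species — with singletons, supply a fallback
variability or use threshold mode. MeTRe compares pairs of species; it
does not by itself correct for unequal sampling depth between species
beyond the arithmetic averaging of pairs.
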