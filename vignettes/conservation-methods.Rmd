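---
title: "Methods: scoring cross-species conservation of RBP binding sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring cross-species conservation of RBP binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbpcons)
```

## The conservation statistic

A whole-genome multiple alignment in MAF format stores, block by block, the
genome segments of many species aligned to a reference. `rbpcons` treats a
block's species roster as the unit of conservation evidence for any short
reference interval inside it: a 20 bp CLIP-seq binding site that falls
fully within a block's reference span is scored

$$P = \frac{N}{\text{totalSpecies}} \times 100,$$

with $N$ the number of *distinct* species contributing at least one row to
that block (reference included). The statistic therefore lives on the
lattice $k/\text{totalSpecies} \times 100$, $k = 1, \dots,
\text{totalSpecies}$, with `totalSpecies = 46` as the default matching the
UCSC 46-way vertebrate alignment.

Assumptions worth keeping in view:

- **Block membership, not column identity.** A species counts as present
  even if its row is gapped over the site's columns. This reads block
  membership as "the locus aligns at all in that species", which is the
  coarse but robust signal available without per-column quality data. A
  per-column mode is deliberately *not* offered: the package computes one
  statistic and computes it consistently.
- **Containment, not overlap.** A site maps only when fully contained in a
  single block's reference span. Sites straddling block boundaries are
  unmapped; they are excluded from every distribution and surface only as
  counts (`n_unmapped`). An alternative treatment scoring unmapped sites
  as $P = 0$ is available via `unmapped_as_zero = TRUE` in
  `profile_rbp()`; exclusion is the default because a site that never
  aligned is evidence of missing data as often as of missing conservation.
- **Duplicate rows collapse.** Paralogous or split alignments giving one
  species several rows in a block count once: $N$ counts species, not
  rows.
- **Multiple containing blocks** (possible in non-multiz inputs) resolve
  to the block with the highest alignment score, ties to the lowest
  reference start. Multiz tilings never trigger this rule, but the
  behaviour must be deterministic when inputs do.

## Random-region nulls

`sample_regions()` draws fixed-length regions uniformly over all eligible
start positions pooled across the intervals of an annotation space, which
weights intervals by eligible length and makes every possible region
equally likely. Overlaps among draws are allowed: with realistic counts
over megabase spaces, collisions are immaterial, while rejection sampling
would bias against long intervals. `null_profile()` scores replicate draws
(default 10) with distinct derived seeds and reports the *minimum* pairwise
rank-sum p-value across replicates as the agreement diagnostic — the
worst-case comparison is the informative one: if even it is unremarkable,
any single replicate is representative.

## Rank-sum testing and ties

`compare_groups()` is the shared two-sided Mann-Whitney machinery. For
groups of at most 50 each it is exact: through the standard null
distribution when values are untied, and through exact enumeration of the
conditional permutation distribution (a dynamic program over doubled
midranks) when ties are present. Larger groups use the tie-corrected
normal approximation. The exact tied path matters in practice: presence
fractions of 37 mammal-like vs 9 lower-vertebrate-like species routinely
tie, and the normal approximation cannot report p-values below roughly
$4 \times 10^{-6}$ at those group sizes no matter how complete the
separation, while the exact enumeration resolves the true tail. Fully tied
samples return $p = 1$.

Inside permutation loops (enrichment), the package uses its own
tie-corrected normal-approximation U test, which matches
`wilcox.test(exact = FALSE)` to machine precision (asserted in the test
suite) at a fraction of the call overhead.

## Family similarity

The similarity score between two RBPs' conservation profiles is
$SS = 2 \cdot NBS / (N_1 + N_2)$, where $NBS$ counts binding sites
conserved in the same percentage of species. The counting rule adopted is
the **multiset intersection**: for each distinct (lattice) value of $P$,
the smaller of the two per-profile counts, summed. It is the only
symmetric rule bounded by $\min(N_1, N_2)$, and it makes self-similarity
exactly 1. P values are rounded to 6 decimals before matching — enough to
absorb floating-point noise, far below the lattice spacing
($100/46 \approx 2.17$).

Evolutionary distances are consumed from a user-supplied Newick tree
(patristic path sums via `ape`); the package does not align protein
sequences or infer trees. No normalization is applied unless
`normalize = TRUE` rescales by the maximum pairwise distance. The
association between similarity and distance is defined as a Pearson
chi-square independence test on quantile-binned pairs (default 3 bins per
axis), run per family by default; with few pairs, expected counts below 5
are flagged rather than silently accepted.

## RReliefF

Feature importance against the continuous response (median conservation
percent per RBP) uses regressional ReliefF: for each instance, its $k$
nearest neighbours under Manhattan distance on min-max-normalized
predictors contribute response and feature differences with exponential
rank weights $\exp(-(r/\sigma)^2)$ normalized to sum 1, accumulating
$N_{dC}$, $N_{dF}$, $N_{dC\wedge dF}$; the weight of feature $F$ is

$$W(F) = \frac{N_{dC \wedge dF}}{N_{dC}} -
         \frac{N_{dF} - N_{dC \wedge dF}}{m - N_{dC}}.$$

Defaults $k = 10$, $m = \texttt{"all"}$, $\sigma = 20$ follow common
RReliefF practice; with `m = "all"` and row-order tie-breaking of equal
neighbour distances the result is fully deterministic. Min-max
normalization makes weights invariant to positive rescaling of any
predictor, and a constant column receives weight exactly 0 (its
differences vanish identically). The feature table must be complete — no
missing-value imputation is attempted at the 60-row scale this targets.
`shuffle_robustness()` permutes one column at a time and flags features
whose median post-shuffle rank falls into the bottom third as
rank-critical.

## Genic thirds

Gene bodies (genomic spans, not spliced transcripts — isoform resolution
is out of scope) are split into three segments whose lengths differ by at
most 1 bp. Remainder base pairs from the integer division go to the
transcriptionally-*last* segments (the 3′ third first, then the middle),
so a 301 bp gene tiles 100/100/101 in transcription order on either
strand; the rule is arbitrary but deterministic and strand-consistent.
Sites are assigned to the segment containing their midpoint
(`floor((start + end)/2)`), one assignment per overlapping gene; the
pairwise region comparisons report raw Wilcoxon p-values per RBP at
$\alpha = 0.05$, with no multiplicity adjustment inside the per-RBP
summary — the "$x$ of $n$ RBPs significant" headline is itself the unit of
interpretation; apply `p.adjust()` downstream when individual RBP calls
matter.

## Permutation enrichment

Gene scores are per-gene medians of site P values (a site mapping to
several genes contributes to each). For a gene set, the overlap with the
scored-gene universe is compared `n_perm` times (default 1000) against
equally sized random draws from the universe *excluding* the overlap — the
standard permutation null; drawing from the full universe is available via
`exclude_overlap = FALSE`. A permutation counts as significant only when
the two-sided U test has $p < 0.05$ *and* the overlap's median exceeds the
draw's: enrichment asks specifically for highly conserved sets, so the
two-sided test is gated one-sidedly. The corrected p-value
$\max(1 - \#\text{sig}/\#\text{total},\ 1/\#\text{total})$ is bounded in
$[1/n_{\text{perm}}, 1]$ by construction. Sets with overlap below 3 are
skipped with a recorded status.

## What the synthetic generators emulate

`synthetic_scenario()` fixes the study conditions the package is validated
under: 46 species — a reference plus 36 mammal-like species at block
retention 0.9 and 9 lower-vertebrate-like at 0.2 — mirroring the 37/9
mammal/lower-vertebrate split and the primate-to-fish conservation
gradient of real vertebrate alignments. Blocks of 40–80 bp tile each
reference chromosome without gaps (a `gap_fraction` can create unaligned
territory); a quarter of blocks are "hot" (retention 0.995/0.7), standing
in for well-conserved loci, and binding sites are planted there while
random nulls sample the whole genome — this is what makes real sites beat
genomic background in the synthetic world, by design rather than by
biology. Sites are 20 bp; a tenth are planted across block boundaries to
exercise the exclusion rule. Feature tables plant one informative feature
(10 percent-points of response per predictor SD against noise SD 3);
gene-score universes plant a +30 shift on 30 of 1000 genes.

What the generators do **not** emulate: substitution processes, indels,
alignment error, per-column quality, GC or repeat structure, overlapping
genes and isoforms, correlated features, or dependence between gene sets.
Passing tests therefore demonstrate that the *computations* recover
planted structure at realistic scales — not that the biological signal in
real CLIP-seq/MAF data behaves this way.

## Problem sizes and numerical choices in the test suite

The suite validates the mapping path against a brute-force containment
scan on 1000 random sites over 200 random blocks; clade recovery on
alignments of ≥ 2000 blocks; RReliefF on 100 seeded 60 × 11 tables plus an
exact 4-instance hand trace (frozen weights $3/35$ and $-3/35$); genic
thirds on 20 synthetic RBPs with a planted 30-point 3′ − 5′ gap
($\sigma = 5$, 50 sites per region) and 200 null replicates at reduced
size; enrichment power and calibration on 50 seeded runs of a 30-gene
planted set in a 1000-gene universe at 1000 permutations. These sizes keep
the full suite around a minute on one core while leaving planted effects
far outside sampling noise. All generators and permutation streams are
seeded; derived child seeds keep independent streams below $2^{31}$.

## Known limitations

- Conservation is block-level presence; nothing is said about motif
  preservation or per-base identity.
- The exon/intron/coding annotation spaces are taken as given intervals;
  merging overlapping transcripts is the caller's responsibility.
- The exact tied rank-sum enumeration is limited to groups of ≤ 50 each;
  beyond that the tie-corrected normal approximation is used.
- `NBS` counting assumes both profiles were scored against the same
  `totalSpecies`; comparing profiles from different alignments is
  meaningless and not guarded beyond the lattice mismatch it produces.
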