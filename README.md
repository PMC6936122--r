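# rbpcons

Cross-species conservation analysis of RNA-binding-protein (RBP) binding
sites.

RBPs steer splicing, stability, localization and translation of RNA
transcripts by binding short recognition elements, and CLIP-seq experiments
catalogue those binding sites genome-wide as 20 bp peaks. `rbpcons` asks how
well such sites are preserved across a whole-genome multiple alignment: for
each binding site it finds the multiz-style MAF alignment block that fully
contains the site's reference coordinates and scores the site by the
percentage of aligned species present in that block,

```
P = (N / totalSpecies) × 100
```

where `N` is the number of distinct species with a row in the block (the
reference included) and `totalSpecies` is the size of the alignment (46 for
the UCSC 46-way vertebrate set). Sites that straddle block boundaries are
unmapped and excluded from distributions (reported as counts). Around this
core statistic the package provides:

- **Random-region nulls** — seeded, length-weighted uniform sampling of
  20 bp regions from genomic/exonic/intronic/coding annotation spaces, with
  replicate agreement diagnostics, for comparing real sites against chance.
- **Per-species presence matrices** — the fraction of an RBP's mapped sites
  whose block contains each species, for contrasting clades (e.g. mammals
  vs lower vertebrates) with Wilcoxon rank-sum tests. Small tied samples
  are tested by exact enumeration of the conditional rank-sum distribution.
- **Family similarity** — for RBP pairs within a family, the similarity
  score `SS = 2·NBS / (N1 + N2)` where `NBS` counts binding sites conserved
  in the same percentage of species (multiset intersection of P values),
  set against patristic distances from a supplied Newick tree, with a
  chi-square independence test on quantile-binned values.
- **RReliefF feature ranking** — regressional ReliefF attribute importance
  of RBP-centric features (site counts, expression, interactions, ...)
  against median conservation, plus shuffle-robustness of the ranking and
  simple regression of conservation on any one feature.
- **Genic thirds** — strand-aware partition of each gene span into equal
  5′/middle/3′ segments, midpoint assignment of scored sites, and pairwise
  rank-sum comparisons of conservation across regions.
- **Phenotype enrichment** — Seten-style score-weighted permutation
  enrichment: per-gene scores are site-P medians; each gene set is compared
  against random gene draws with Mann-Whitney U tests over 1000
  permutations and summarized as
  `corrected p = max(1 − #significant/#total, 1/#total)`.
- **Synthetic data** — generators for MAF/BED/GMT/tree/feature-table
  fixtures with planted clade structure, mappability, positional bias,
  informative features and high-scoring gene sets, so the entire pipeline
  is testable end to end with known ground truth.

## Worked example

```r
library(rbpcons)

sc <- synthetic_scenario(chrom_lengths = c(chr1 = 30000), n_rbps = 2,
                         sites_per_rbp = 150, seed = 7)
maf   <- simulate_maf(sc)
index <- index_blocks(read_maf(text = maf$maf))
sites <- simulate_sites(sc, maf)

prof <- profile_rbp(sites$sites$RBP01, index, total_species = 46,
                    rbp_name = "RBP01")
prof
#> conservation_profile 'RBP01': 150 sites (138 mapped, 12 unmapped), median P = 93.5

nulls <- sample_regions(genomic_space(sc$chrom_lengths), 150, 20, seed = 8)
null_prof <- profile_rbp(nulls, index, 46, "genomic_null")
null_prof
#> conservation_profile 'genomic_null': 150 sites (107 mapped, 43 unmapped), median P = 80.4

compare_groups(prof$records$P[prof$records$mapped],
               null_prof$records$P[null_prof$records$mapped])$p.value
#> 4.51e-16
```

150 simulated binding sites of `RBP01` were planted inside well-conserved
("hot") alignment blocks, with a tenth deliberately straddling block
boundaries — 12 came back unmapped, close to the planted rate. Their median
conservation (93.5% of the 46 species) clearly exceeds the genomic null's
80.4%, and the rank-sum test confirms the separation. Feature ranking on a
synthetic table with one informative feature recovers it at the top:

```r
ft <- simulate_feature_table(seed = 9)
head(sort(rrelieff(ft$x, ft$y)$weights, decreasing = TRUE), 3)
#>        n_binding_sites tissue_specificity_tau   rbp_rbp_interactions
#>            0.115026678            0.006273052           -0.003544666
```

`run_pipeline(pipeline_config("run1", seed = 1))` executes all stages in
order and writes TSV outputs plus a checksummed manifest;
`inst/cli/rbpcons.R` wraps the same functions as a command-line tool
(`Rscript inst/cli/rbpcons.R run-all --out-dir run1 --seed 7`).

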