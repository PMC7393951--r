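# hadalsig

Comparative-genomics signatures of hadal (deep-trench) adaptation in
clades of single amplified genomes (SAGs).

## The problem

Heterotrophic bacteria recovered from hadal trenches (6,000–11,000 m)
often cluster phylogenetically with surface-water relatives, yet recruit
far more metagenomic reads at depth. The question is *what changed*: which
gene content is private to the trench lineages, which protein families
diverged fastest, whether that divergence looks selected or neutral, and
how the lineages distribute over the water column. `hadalsig` implements
that comparison as a tested, seeded pipeline for anyone analysing a focal
set of genomes against reference relatives — SAGs against isolate genomes
being the motivating case.

## What it computes

| Stage | Statistic |
|---|---|
| Relative selection | Fragment-based ANI; background genomes kept iff ANI > 95% to ≥ 1 focal genome |
| Pangenome | Reciprocal-best-hit gene clusters (BLOSUM62, affine 11/1); majority-rule category; focal-unique clusters; category composition of unique vs all annotated clusters |
| Variation | Per-gene top-hit identity against background proteomes; decile ranking by dissimilarity `100 − identity`; per-category Pearson `r` of within-decile abundance vs mean dissimilarity, two-sided *p* from `t = r·√((n−2)/(1−r²))` |
| Codon usage | Wright's ENC `= 2 + 9/F₂ + 1/F₃ + 5/F₄ + 3/F₆` (range 20–61), GC3, the null curve `ENC* = 2 + s + 29/(s² + (1−s)²)`, below-curve classification, unique-vs-all ENC per category |
| Recruitment | Competitive read assignment (highest identity wins), `RPKG = (Rx/MG)/Gx`, per-genome Z-normalised depth profiles, complete-linkage clustering |

A synthetic clade generator (`simulate_clade()`) with full ground truth —
planted ANI, ortholog families, unique genes, per-category divergence
multipliers, codon-bias gradients and depth-structured abundances —
drives parameter-recovery tests for every stage.

## Worked example

Simulate a clade of 2 focal SAGs and 3 background relatives (one of them
distant), with mobilome (X) genes planted at twice the amino-acid
divergence of other categories, and run everything:

```r
library(hadalsig)
cfg <- pipeline_config(seed = 7, out_dir = "demo_out",
  clade = list(n_focal = 2, n_background = 3, n_core_genes = 120,
               gene_length_codons = c(60L, 120L),
               ani_targets = c(0.02, 0.02, 0.02, 0.02, 0.2),
               unique_genes_per_focal = 8,
               aa_divergence_base = 0.05,
               core_category_weights = c(C=1,E=1,G=1,J=1,K=1,L=1,
                                         M=1,O=1,P=1,T=1,X=2),
               divergence_class_by_category = c(X = 2),
               annotated_fraction = 0.85),
  n_reads_per_sample = 5000)
run <- run_pipeline(cfg)
run
#> <hadalsig pipeline run>
#>   genomes: 5 | close relatives selected: 2
#>   gene clusters: 136 | focal-unique: 16
#>   categories with significant positive variation correlation: X
```

The ANI stage keeps the two genuine relatives and drops the distant one
(planted at 20% divergence):

```r
run$ani_table[1:4, c("genome_a", "genome_b", "ani_percent")]
#>   genome_a genome_b ani_percent
#>        F01      F02       95.29
#>        F01      B01       96.04
#>        F01      B02       96.07
#>        F01      B03       78.62
```

Mobilome genes are over-represented among the focal-unique clusters
(27% of unique vs 12% of all annotated clusters) and their proteins
diverge fastest — the decile correlation recovers the planted 2×
multiplier:

```r
cc <- run$variation$correlations
cc[which(cc$significant), c("category", "pearson_r", "p_value")]
#>  category pearson_r  p_value
#>         X      0.95 2.64e-05
```

Depth profiles reverse between surface and trench, as planted: RPKG of
the focal genomes rises ~20-fold from 0 m to 9,000 m while the background
relatives collapse:

```r
round(run$recruitment$rpkg[, c(1, 5)], 2)
#>     S01_0m S05_9000m
#> F01   0.83     28.79
#> F02   0.87     12.03
#> B01  18.05      1.90
#> B02  15.01      1.35
#> B03  13.74      1.78
```

Every stage also writes TSV outputs (plus a Newick dendrogram and a JSON
run manifest recording the seed and all thresholds) under `out_dir`;
reruns with the same seed are byte-identical.

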