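---
title: "Methods: detecting hadal-adaptation signatures in SAG clades"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting hadal-adaptation signatures in SAG clades}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hadalsig)
```

## The analysis

Single amplified genomes (SAGs) recovered from hadal trench water can be
compared with reference genomes of shallow-water relatives to ask which
parts of the genome changed on the way down. `hadalsig` implements that
comparison as a chain of self-contained stages, each with an explicit
statistical contract:

1. **ANI and relative selection.** Pairwise average nucleotide identity
   between all genomes; background genomes with ANI strictly greater than
   95% to at least one focal SAG are kept as "close relatives".
2. **Pangenome.** Ortholog gene clusters across focal and selected
   background genomes; clusters whose members occur only in focal genomes
   are the *unique* clusters; their one-letter functional-category
   composition is compared against the whole annotated cluster pool.
3. **Amino-acid variation.** Each annotated focal protein is searched
   against the pooled background proteomes; genes are ranked by
   dissimilarity to their top hit (100 − identity), split into ten
   equal intervals, and each category's per-interval relative abundance is
   correlated (Pearson) with the interval's mean dissimilarity.
4. **Codon usage.** Wright's effective number of codons (ENC) and GC3 per
   gene, the expected ENC–GC3 curve under random codon usage, below-curve
   classification, and a unique-versus-all ENC comparison per category.
5. **Recruitment.** Metagenomic reads are mapped competitively (each read
   recruited only by the genome with which it aligns at the highest
   identity), abundances are expressed as RPKG, Z-normalised per genome
   across the depth profile and clustered hierarchically.

A synthetic clade generator with full ground truth drives validation of
every stage.

## ANI: fragment method

No single "ANI" exists; published values depend on the tool. We use the
classic fragment formulation because it is reproducible and exactly
checkable on substitution-only simulations: each query genome is cut into
consecutive non-overlapping 1000 bp windows (terminal remainders
discarded), each window is placed in the target genome by exact 15-mer
seeding on both strands and extended without gaps, and windows with an
aligned fraction ≥ 0.7 and identity ≥ 30% contribute to the mean. The
reported value averages both directions. On substitution-only clades the
estimator recovers planted divergences of 1, 5 and 10% within ±0.5
percentage points (tested). Because the extension is ungapped, genomes
with indel divergence need an external ANI tool; that regime is out of
scope here.

The >95% relative-selection boundary is strict: a background genome at
exactly 95.0% is not selected.

## Ortholog clustering: RBH + connected components

Proteome comparison uses global Needleman–Wunsch alignment with BLOSUM62
and affine gaps (open 11, extend 1 — the common protein-search defaults).
Candidate pairs must share at least one exact amino-acid 4-mer; each
gene's best-scoring hit per partner genome is computed, mutual best hits
that pass identity ≥ 30% and shorter-sequence coverage ≥ 0.5 become
edges, within-genome pairs above 70% identity bridge recent paralogs, and
ortholog clusters are the connected components (singletons included as
clusters). This replaces MCL-style orthogroup inference with a procedure
whose behaviour is fully determined by the thresholds above; on simulated
clades without paralogs and with ≤ 10% divergence it reproduces the
planted families exactly (tested, fixed seeds).

Cluster annotation is majority rule over annotated members; ties are
broken by the lexicographically smallest category letter so runs are
deterministic. Unannotated clusters are excluded from both denominators
of the composition comparison, which therefore speaks only about
annotated clusters.

## Variation deciles

The top-hit search mirrors a blastp best-hit protocol, with one
deliberate substitution: instead of an E-value cutoff (which depends on
database size), a raw alignment-score threshold decides whether a query
has a hit. `calibrate_score_threshold()` aligns residue-shuffled decoys
and returns the score quantile below which random pairs fall, so the
default can be recalibrated for any proteome; genes without an accepted
hit are excluded from ranking, as a blastp E-value cutoff would silently
do.

Ranked genes are divided into ten intervals whose sizes differ by at most
one (larger intervals first, ties in dissimilarity broken by gene id).
"Relative abundance" is the within-interval proportion among annotated
genes (each interval's proportions sum to one); the alternative reading —
the fraction of a category's genes falling in the interval — is not used
because the stacked-bar presentation this analysis feeds normalises
within intervals. Pearson correlation of a category's ten proportions
against the ten interval means of dissimilarity is tested two-sided via
the t statistic on eight degrees of freedom; sidedness is a choice we
make explicit, and the significance cutoff (p < 0.01) is a parameter.

## ENC, GC3 and the null curve

ENC is computed per gene as `2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, where `Fk`
averages the codon homozygosity `F̂ = (n·Σp̂² − 1)/(n − 1)` over the
families of degeneracy class *k*. Conventions follow the classic
implementation: Leu/Ser/Arg are treated as one 6-fold class rather than
2+4 subfamilies; a missing 3-fold class (Ile unobserved) is imputed as
`(F2 + F4)/2`; any other missing class makes ENC undefined; finite-sample
values above 61 are truncated to 61. A gene using one codon per amino
acid gives exactly 20 and equal synonymous usage gives exactly 61 after
truncation (both tested, plus equivalence with an independently coded
step-by-step oracle to 1e-9).

GC3 is the G+C fraction of third positions over all sense codons (not the
synonymous-only GC3s variant; plots from tools using GC3s will differ
slightly). The null curve is `ENC* = 2 + s + 29/(s² + (1 − s)²)`.

One empirical subtlety the tests encode: with *uniform* synonymous usage
the true ENC (61) sits barely above the curve's maximum (60.5), and
finite-gene sampling noise in ENC is of order ±1 even at 2000 codons, so
10–20% of unbiased genes fall below the curve by chance. "Lying well
below the curve" is therefore informative only as a contrast: at bias
strength 0 the below-curve fraction stays ≤ 0.3 while at strength 0.8 it
is 1 (tested). Per-gene below-curve flags should be read accordingly.

## Recruitment and RPKG

External BLAST tabular (outfmt 6) hits are supported directly; query
coverage is computed from the best HSP span (no multi-HSP stitching). The
internal mapper is a deliberately simple stand-in for a read aligner:
exact 21-mer seeding on both strands, ungapped full-length placement,
identity over the read length. Filters default to the standard values
(E ≤ 1e-5 where an E-value exists, identity ≥ 95, coverage ≥ 80, all
inclusive), and competitive assignment takes the highest identity with
deterministic tie-breaks (score, then lexicographic genome id).

RPKG is `(Rx/MG)/Gx` — reads per kilobase of genome per gigabase of
metagenome — so doubling either the genome or the metagenome halves the
value. Depth profiles are Z-normalised per genome with the sample
(n − 1) standard deviation; constant rows map to zero. Hierarchical
clustering uses Euclidean distance and complete linkage (configurable),
with rows pre-sorted by genome id for deterministic leaf order, and the
dendrogram serialises to Newick.

## The synthetic clade generator

The generator emulates the statistical structure the analysis assumes,
with every parameter surfaced in `clade_config()`:

* A clade ancestor of `n_core_genes` single-copy genes (default 120,
  80–250 codons) with intergenic spacers; codon usage is drawn from
  Zipf-like per-family weights ranked GC-ending first, scaled by
  `codon_bias_strength` (0 = uniform synonymous usage).
* Each genome derives from the ancestor by codon-aware point
  substitutions only — no indels or rearrangements, so nucleotide and
  protein divergences are exact Hamming counts and every oracle is exact.
  Nonsynonymous changes are sized by the genome's base amino-acid
  divergence times its category's multiplier
  (`divergence_class_by_category`); synonymous and intergenic changes top
  the genome up to its `ani_target`. The default per-genome divergence
  (0.02 from the ancestor, hence ~96% pairwise ANI) matches a clade whose
  relatives pass the >95% selection rule.
* Focal genomes receive private genes drawn from
  `unique_category_weights` (default enriched for mobilome X and envelope
  biogenesis M, the signature the analysis is designed to detect), with
  their own codon-bias strength.
* Sample abundances follow a log-linear depth model — focal genomes gain,
  background genomes lose `focal_depth_gain` log-units across the depth
  range, with lognormal noise — and reads are drawn proportional to
  abundance × genome length so that RPKG, which divides by genome
  length, recovers the configured abundances. Read errors are i.i.d.
  substitutions.

What the generator does **not** emulate: indels and rearrangements,
horizontal transfer of shared accessory genes, amplification bias and
incomplete SAGs, chimeric reads, quality scores, and compositional
heterogeneity along the genome. Passing recovery tests therefore shows
the estimators are correct under substitution-only evolution with
complete genomes, not that real SAG data meets those assumptions; with
real data the ANI and clustering stages in particular should be expected
to degrade with assembly incompleteness.

## Numerical and design choices

* Alignment traceback tie-breaks prefer match, then gap-in-subject, then
  gap-in-query, so identities are reproducible across co-optimal
  alignments; the affine convention charges `open + ext·L` for a gap of
  length L.
* Gene tables use 1-based inclusive coordinates on the forward strand;
  strand `-` means the CDS is the reverse complement of the slice.
* Codons containing non-ACGT bases translate to X and are skipped by the
  codon-usage counters; internal stop codons are hard errors everywhere.
* All randomness flows through R's RNG: `clade_config()` requires a seed,
  reruns of `run_pipeline()` with the same config are byte-identical, and
  the run manifest records the seed and every threshold actually used.
* Problem sizes in the test-suite simulations (tens of genomes maximum,
  hundreds of gene families, 50,000 reads) were chosen as the smallest
  sizes at which the binomial/Poisson noise floors sit comfortably below
  the tested tolerances, e.g. ±0.5 ANI points at ~100 fragments per
  genome pair.

## Known limitations

* Ungapped ANI extension and the ungapped internal mapper make the
  simulator's substitution-only assumption load-bearing; for real data,
  import external BLAST hits instead of using the internal mapper.
* The score-threshold stand-in for an E-value cutoff is calibrated for
  false acceptance, not false rejection; very short or compositionally
  biased proteins may need a recalibrated threshold.
* Single-copy orthology only: gene families with in-paralogs beyond the
  70%-identity bridge will fragment or merge clusters.
* The composition comparison is descriptive (proportions), matching the
  source analysis; it deliberately attaches no enrichment p-values.
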