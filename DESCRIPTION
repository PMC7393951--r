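Package: hadalsig
Title: Comparative Genomic Signatures of Hadal Adaptation in Single
    Amplified Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects genomic signatures of hadal (deep-trench) adaptation
    in clades of single amplified genomes (SAGs) compared with shallow-water
    relatives.  Implements fragment-based average nucleotide identity (ANI)
    and ANI-threshold selection of close relatives, reciprocal-best-hit
    ortholog gene clustering with majority-rule functional annotation,
    detection and functional-composition analysis of focal-unique gene
    clusters, rank-decile profiling of amino-acid sequence variation with
    per-category Pearson correlation tests, Wright's effective number of
    codons (ENC) with GC3 and the expected ENC-GC3 curve under random codon
    usage, and competitive metagenomic read recruitment with RPKG depth
    profiles, Z-normalisation and hierarchical clustering.  A seeded
    synthetic clade generator with full ground truth supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    igraph,
    ape,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
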