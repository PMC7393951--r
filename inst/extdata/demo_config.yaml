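# Demo pipeline configuration: 2 focal SAGs + 3 background relatives (one
# distant), mobilome (X) genes planted at twice the base amino-acid
# divergence, 5000 reads per depth sample.  See README.md for the outputs.
seed: 7
out_dir: demo_out
clade:
  n_focal: 2
  n_background: 3
  n_core_genes: 120
  gene_length_codons: [60, 120]
  ani_targets: [0.02, 0.02, 0.02, 0.02, 0.2]
  unique_genes_per_focal: 8
  aa_divergence_base: 0.05
  core_category_weights: {C: 1, E: 1, G: 1, J: 1, K: 1, L: 1, M: 1, O: 1,
                          P: 1, T: 1, X: 2}
  divergence_class_by_category: {X: 2}
  annotated_fraction: 0.85
n_reads_per_sample: 5000
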