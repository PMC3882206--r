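# Fully synthetic end-to-end run with reduced permutation counts.
# Omitted keys fall back to the documented defaults
# (B_meta 100000, B_genes/B_module/n_boot 1000, gates 0.01/0.1, FDR 0.10).
seed: 1
synthetic:
  n_genes: 200
  n_pairs: 3
  rho: 0.6
  n_per_pattern: 8
  n_individuals: 12
permutations:
  B_meta: 500
  B_genes: 300
  B_module: 300
  n_boot: 300
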