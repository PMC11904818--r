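# Study configuration shared by the numbered analysis scripts.
# Two Visium-like muscle samples from contrasting breeds (obese vs lean),
# one snRNA-seq reference of eight cell populations, and three planted
# secretory->target gene correlations that the niche-correlation stage
# should recover.
seed: 20260921
out_dir: results/study
samples:
  TB:
    condition: obese
    grid_rows: 64
    grid_cols: 64
    reads_per_spot: 6000
  Duroc:
    condition: lean
    grid_rows: 64
    grid_cols: 64
    reads_per_spot: 9000
planted_pairs:
  gene_a: [GENE00300, GENE00302, GENE00304]
  gene_b: [GENE00350, GENE00352, GENE00354]
  rho: [0.7, 0.4, 0.0]
correlation:
  n_regions_per_sample: 200
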