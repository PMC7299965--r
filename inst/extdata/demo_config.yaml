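# Demo configuration: synthetic cohort, full pipeline.
seed: 1
synthetic:
  n_per_group: 8
  n_normal: 8
  n_genes: 120
  n_cpgs: 1200
  n_window_cpgs: 200
options:
  w_pos: 0.6
  core_basal_threshold: 0.6
  flank_bp: 50000
  fdr_alpha: 0.05
  effect_top_fraction: 0.2
  knn_k: 10
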