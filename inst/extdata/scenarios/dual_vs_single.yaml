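# Four motility levels standing in for cell lines of graded migratory
# capacity, each quantified by the dual-image method (per-well detected
# ROIs) and the single-image method (one standard ROI pair).
name: dual_vs_single
replicates: 6
paired_motility_seeds: true
outputs: [dual, single]
base_config:
  n_cells: 30000
  duration: 24
arms:
  fast_epithelial:
    speed_multiplier: 1.2
  moderate_epithelial:
    speed_multiplier: 1.0
  slow_carcinoma:
    speed_multiplier: 0.55
  fibroblast:
    speed_multiplier: 0.45
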