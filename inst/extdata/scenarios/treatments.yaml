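# Pharmacological panel: actin depolymerization suppresses speed, a
# cell-cycle antagonist blocks division, serum + ECM coating stimulates
# motility. Multipliers are scenario choices giving the qualitative
# directions of the corresponding wet-lab treatments.
name: treatments
replicates: 8
paired_motility_seeds: true
outputs: [dual]
base_config:
  n_cells: 30000
  duration: 24
  division_rate: 0.028881132523331052
arms:
  control: {}
  cytoD:
    speed_multiplier: 0.1
  MMC:
    division_multiplier: 0.0
  serum_ECM:
    speed_multiplier: 1.5
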