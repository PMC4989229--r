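# Headline demonstration: paired wells, division off vs on (population
# doubling in 24 h), read out by the lineage-dye statistic and by the
# conventional nuclear-signal statistic referenced to the parental
# population.
name: insensitivity
replicates: 30
paired_motility_seeds: true
outputs: [dual, count_based]
base_config:
  n_cells: 30000
  duration: 24
arms:
  division_off:
    division_rate: 0.0
  division_on:
    division_rate: 0.028881132523331052  # log(2)/24: one doubling per day
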