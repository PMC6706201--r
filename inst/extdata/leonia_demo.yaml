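# Demo scenario: dense understory-tree system (small crops, trap-lining,
# 8 adults/ha, gut passage 120-240 min, only 8 focal trees fruiting, other
# species supply energy in the IBM). Sizes kept small for a fast run.
species: leonia
scenario:
  n_days: 31
  n_offspring: 120
  n_gut_obs: 3
parentage:
  n_confidence_sims: 1500
  min_typed_loci: 6
ibm:
  n_days: 50
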