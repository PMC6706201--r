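# Demo scenario: sparse canopy-tree system (large fruit crops, revisits,
# ~1 adult/ha, gut passage 30-240 min). Sizes kept small for a fast run.
species: parkia
scenario:
  n_days: 31
  n_offspring: 120
  n_gut_obs: 196
parentage:
  n_confidence_sims: 1500
ibm:
  n_days: 50
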