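# Default Monte Carlo experiment: calibrated synthetic population, six
# scenarios, three designs, both bias variants.
population:
  params: {}
iterations: 1000
master_seed: 1
spr_variance_mode: corrected
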