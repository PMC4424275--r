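# Sample-size configuration: 375 plots assessed per occasion in each design.
- design: spr
  n_t1_only: 125
  n_permanent: 250
  n_t2_only: 125
- design: cfi
  n_permanent: 375
- design: temporary
  n_t1_only: 375
  n_t2_only: 375
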