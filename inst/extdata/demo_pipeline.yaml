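seed: 1
n_per_family: 20
substitution_rate: 0.02
motif_rate_multiplier: 0.2
bootstrap_replicates: 100
threshold: 1.0e-5
patterns:
  typeIIb: FxGxxxHxxxH
  FMO_like: FxGxxxHxxx[YF]
  BVMO: FxGxxxHxxxW
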