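# Default synthetic benchmark scenario: a 20-species community spanning
# 8 orders of magnitude in body mass, with ADBM ground-truth parameters.
S: 20
log10_mass_bounds: [-6, 2]
true_params:
  a: 1.0e-3     # log10 a = -3
  ai: 0.5
  aj: 0.5
  b: 0.1
removal_prob: 0.2
seed: 1
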