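# Default factorial design levels: 3 ICC x 4 cluster numbers x 3 reliability
# pairs x 3 effect sizes x 2 effect-size variances = 216 conditions.
icc: [0.1, 0.3, 0.5]
n_dyads: [50, 150, 250, 400]
reliability:
  - [0.7, 0.7]
  - [0.8, 0.8]
  - [0.7, 0.8]
effect_size: [0.2, 0.5, 0.8]
es_var: [0.5, 1.0]
distinguishable: true
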