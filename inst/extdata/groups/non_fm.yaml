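label: NON_FM
'n': 154
mu: -0.0685358
rho: 0.2042841
item_offsets:
  B_UPPER: -0.3
  B_ARM: -0.1
  B_LEG: -0.2
  PAIN_FREQ: -0.4
  PAIN_KINDS3: 0.2
  TIRED_FREQ: 0.1
  EFFORT: 0.0
  SYMPT7: 0.4
  RECOG: 0.3
miss_rates:
  q1: 0.00566
  q2: 0.00566
  q3: 0.00566
  q4: 0.00566
  q5: 0.00566
  q6: 0.00566
  q13: 0.00566
ordinal_gap: 1.0
region_extra_p: 0.3
trunk_offset: 1.5
seed: 204
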