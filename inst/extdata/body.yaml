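height: 1.7
mass: 65.0
d:
- 1.0
- 1.0
- 1.0
d4_ext: 10.0
d4_flex: 10.0
seat_offset: 0.0663
fractions:
  length:
    shank: 0.246
    thigh: 0.245
    pelvis: 0.078
    hat: 0.4
  mass:
    shank: 0.093
    thigh: 0.2
    pelvis: 0.142
    hat: 0.497
  com:
    shank: 0.567
    thigh: 0.567
    pelvis: 0.5
    hat: 0.626
  gyration:
    shank: 0.303
    thigh: 0.323
    pelvis: 0.31
    hat: 0.496
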