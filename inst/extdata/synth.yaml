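seed: 1.0
height: 1.7
mass: 65.0
duration: 3.0
seat_off: 1.0
noise_sd: 0.05
synergy_centers:
- 15.0
- 40.0
- 65.0
- 85.0
synergy_widths:
- 9.0
- 9.0
- 10.0
- 12.0
synergy_levels:
- 0.8
- 0.85
- 0.8
- 0.6
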