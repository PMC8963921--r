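TA:
  fmax: 1000.0
  l_opt: 0.31
  v_max: 1.9
  r:
    ankle: -0.04
    knee: 0.0
    hip: 0.0
    lumbar: 0.0
  l_ref: 0.31
  theta_ref:
    ankle: 0.0
    knee: 0.0
    hip: 0.0
    lumbar: 0.0
SOL:
  fmax: 3500.0
  l_opt: 0.26
  v_max: 1.6
  r:
    ankle: 0.048
    knee: 0.0
    hip: 0.0
    lumbar: 0.0
  l_ref: 0.26
  theta_ref:
    ankle: 0.0
    knee: 0.0
    hip: 0.0
    lumbar: 0.0
GAS:
  fmax: 1500.0
  l_opt: 0.39
  v_max: 2.3
  r:
    ankle: 0.048
    knee: 0.02
    hip: 0.0
    lumbar: 0.0
  l_ref: 0.39
  theta_ref:
    ankle: 0.0
    knee: 0.0
    hip: 0.0
    lumbar: 0.0
RF:
  fmax: 1200.0
  l_opt: 0.36
  v_max: 2.2
  r:
    ankle: 0.0
    knee: -0.048
    hip: -0.04
    lumbar: 0.0
  l_ref: 0.36
  theta_ref:
    ankle: 0.0
    knee: 0.0
    hip: 0.0
    lumbar: 0.0
VAS:
  fmax: 4000.0
  l_opt: 0.33
  v_max: 2.0
  r:
    ankle: 0.0
    knee: -0.045
    hip: 0.0
    lumbar: 0.0
  l_ref: 0.33
  theta_ref:
    ankle: 0.0
    knee: 0.0
    hip: 0.0
    lumbar: 0.0
BFL:
  fmax: 1300.0
  l_opt: 0.44
  v_max: 2.6
  r:
    ankle: 0.0
    knee: 0.025
    hip: 0.055
    lumbar: 0.0
  l_ref: 0.44
  theta_ref:
    ankle: 0.0
    knee: 0.0
    hip: 0.0
    lumbar: 0.0
BFS:
  fmax: 800.0
  l_opt: 0.27
  v_max: 1.6
  r:
    ankle: 0.0
    knee: 0.025
    hip: 0.0
    lumbar: 0.0
  l_ref: 0.27
  theta_ref:
    ankle: 0.0
    knee: 0.0
    hip: 0.0
    lumbar: 0.0
GMAX:
  fmax: 2500.0
  l_opt: 0.33
  v_max: 2.0
  r:
    ankle: 0.0
    knee: 0.0
    hip: 0.06
    lumbar: 0.0
  l_ref: 0.33
  theta_ref:
    ankle: 0.0
    knee: 0.0
    hip: 0.0
    lumbar: 0.0
RA:
  fmax: 900.0
  l_opt: 0.3
  v_max: 1.8
  r:
    ankle: 0.0
    knee: 0.0
    hip: 0.0
    lumbar: -0.08
  l_ref: 0.3
  theta_ref:
    ankle: 0.0
    knee: 0.0
    hip: 0.0
    lumbar: 0.0
ES:
  fmax: 2000.0
  l_opt: 0.25
  v_max: 1.5
  r:
    ankle: 0.0
    knee: 0.0
    hip: 0.0
    lumbar: 0.058
  l_ref: 0.25
  theta_ref:
    ankle: 0.0
    knee: 0.0
    hip: 0.0
    lumbar: 0.0
IL:
  fmax: 1500.0
  l_opt: 0.3
  v_max: 1.8
  r:
    ankle: 0.0
    knee: 0.0
    hip: -0.035
    lumbar: 0.0
  l_ref: 0.3
  theta_ref:
    ankle: 0.0
    knee: 0.0
    hip: 0.0
    lumbar: 0.0
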