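# stsnorm

EMG normalization for sit-to-stand (STS) analysis **without maximum voluntary
contraction (MVC)** — for researchers studying longitudinal muscle-activity
change in populations that cannot produce an MVC reference, such as subacute
stroke survivors, plus the downstream muscle-tension and muscle-synergy
analyses those studies need.

## The method

Comparing EMG amplitude across measurement days requires a normalization
reference. MVC is infeasible after motor paralysis, and within-task peak
normalization erases amplitude information (every day's peak becomes 100%).
`stsnorm` instead uses the STS movement's own joint torques as the
calibration signal:

1. **Inverse dynamics** — joint torques `T_jnt` at ankle, knee, hip and
   lumbar from a four-link sagittal skeletal model, given joint angles and
   hip/foot reaction forces, including joint-type-specific resistance
   (viscous at leg joints, angle-proportional with a ±0.0314 rad dead zone
   at the lumbar joint).
2. **Forward simulation** — the same torques from muscle tensions in a
   Hill-type model of 11 uni-/bi-articular muscles
   (`F = Fmax · f_fl(l̂) · f_fv(v̂) · m̂ + F_PE(l̂)`, with
   `f_fl = exp(-(l̂-1)²)`, `f_fv = 1 + tanh(3 v̂)`), mapped through signed
   moment arms `τ_k = Σᵢ r_ki Fᵢ`.
3. **Constrained optimization** — per-muscle positive scales `αᵢ` with
   `m̂ᵢ(t) = αᵢ eᵢ(t)` minimize
   `Z = ‖T_max − τ_max‖² + ‖T_min − τ_min‖²` subject to
   `0 ≤ αᵢ eᵢ(t) ≤ 1`. A pure positive rescaling keeps Pearson r = 1 and
   identical on/off timing between normalized activation and measured
   envelope, while the torque extrema pin the amplitude scale.

Normalized activations then feed muscle-tension estimates, muscle-synergy
extraction by non-negative matrix factorization (`M ≈ W C`, four synergies
for STS), and nonparametric longitudinal statistics (Wilcoxon rank-sum for
two measurement days, Kruskal–Wallis for three or more). A synthetic STS
generator with full ground truth (known activations, scales, synergies,
torques, seat-off) makes the entire pipeline testable end to end.

## Worked example

```r
library(stsnorm)

cfg   <- synth_config(seed = 42)        # 3 s trial, seat-off at 1 s, 5% EMG noise
trial <- gen_trial(cfg)                 # raw EMG / angles / force-plate streams
pt    <- preprocess_trial(trial$recording)   # envelopes, filtering, seat-off, window
body  <- body_model(height = 1.70, mass = 65)
res   <- analyze_trial(pt, body, seed = 42)  # inverse dynamics -> normalization -> synergies

round(res$norm$alpha, 3)
#>     TA    SOL    GAS     RF    VAS    BFL    BFS   GMAX     RA     ES     IL
#>  2.330  0.001  0.001  0.001  1.844  2.571 38.772  0.361  0.254  0.847  0.415
```

The scale factors are the normalization: multiplying each measured envelope
by its `α` gives the normalized activation. Muscles whose `α` sits at a
bound are flagged with warnings — there the inverse-dynamics extrema lie
outside the attainable torque envelope (the method's honest failure mode;
the residual is reported as `res$norm$Z`).

```r
m <- evaluate_fit(res$norm$m_hat[, measured_muscle_names()],
                  as.matrix(pt$envelopes), res$norm$tau_sim, res$torques_id)
range(m$pearson_r)
#> [1] 1 1
round(m$percent_re, 2)          # torque-maximum relative error per joint
#>  ankle   knee    hip lumbar
#>  43.08   5.56   0.00   0.00
res$synergies$reconstruction_quality
#> [1] 100
res$features
#>   synergy peak_level peak_time_pct
#> 1       1      0.499            15
#> 2       2      0.979            40
#> 3       3      0.953            65
#> 4       4      0.463            82
```

Every normalized activation correlates perfectly (r = 1) with its measured
envelope — the defining property of the scaling construction — while the
synergy features (peak level and peak timing of the four temporal patterns)
recover the generator's ground-truth bumps at 15/40/65/85% of motion
progress. `run_pipeline()` chains this over many trials and days and writes
a `summary.tsv` of per-muscle tension changes and per-synergy peak changes
with rank-test p-values.

A thin command-line front end is available at `inst/scripts/stsnorm`
(subcommands `simulate`, `preprocess`, `invdyn`, `normalize`, `synergy`,
`pipeline`).

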