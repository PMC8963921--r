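---
title: "Joint-torque-based EMG normalization for sit-to-stand: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint-torque-based EMG normalization for sit-to-stand: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stsnorm)
```

## The problem

Comparing surface-EMG amplitudes across measurement days — the core of any
longitudinal study of muscle-activity recovery — requires normalization,
because electrode placement and skin condition change between sessions. The
conventional reference is the maximum voluntary contraction (MVC), which many
subacute stroke survivors cannot produce. Normalizing to the within-task peak
instead destroys exactly the amplitude information a longitudinal comparison
needs: every day's peak becomes 100% by construction.

`stsnorm` implements an alternative that needs no voluntary reference: the
joint torques of the sit-to-stand (STS) movement itself act as the
calibration signal. Joint torques can be computed from kinematics and
reaction forces alone (inverse dynamics); the same torques can be simulated
from EMG-driven muscle activations through a Hill-type musculoskeletal model
(forward dynamics). A per-muscle positive scale factor applied to the
measured EMG envelope is then chosen so the two torque computations agree at
their extrema. The scaled envelope is the normalized activation.

## Skeletal model and inverse dynamics

The body is a four-link planar chain — shank, thigh, pelvis, HAT
(head-arms-trunk) — hinged at ankle, knee, hip and lumbar joints, with the
ankle as the grounded root (the feet stay still during STS, so the foot is
not modeled). Joint angle $\theta_k$ is the counter-clockwise rotation of
segment $k$ relative to segment $k-1$, zero at upright stance; this single
convention also fixes the signs of all muscle moment arms.

Joint torques satisfy the chain's equation of motion

$$I(\Theta,\dot\Theta)\,\ddot\Theta + H(\Theta,\dot\Theta) + g(\Theta)
  + \Psi(\Theta,\dot\Theta) = T_{\mathrm{jnt}} + \Phi,$$

assembled per sample from the planar Lagrangian in absolute segment angles
and mapped to joint coordinates (`inverse_dynamics()`). $\Psi$ is a joint
resistance: viscous ($d_k \dot\theta_k$) at ankle, knee and hip,
angle-proportional at the lumbar joint with separate extension/flexion
coefficients outside a $\pm 0.0314$ rad dead zone, inside which it is zero.
The dead-zone map is discontinuous at its edges; that is accepted as
defined. $\Phi$ is the generalized torque of the seat reaction, applied at a
configurable point on the pelvis and set to zero from seat-off onward. Foot
forces act at the grounded root, so their generalized torque on the chain is
identically zero; they are carried as data for balance checks.

Anthropometry is scaled from subject height and mass by an editable fraction
table (`default_body_fractions()`); the shipped values are literature-order
figures for adult bodies, and the viscous coefficients default to small
published-order magnitudes ($d = 1$ N m s/rad, lumbar 10 N m/rad), all
overridable through `body.yaml`. Muscle-tension estimates are known to be
sensitive to such generic parameters; the package treats them as explicit
configuration rather than constants.

### Verifying the dynamics

Three independent oracles pin the implementation: a static per-segment
moment balance (agreement to $10^{-8}$ N m), the closed-form compound
pendulum when distal segments are massless ($10^{-6}$), and an energy
balance (joint power equals the derivative of mechanical energy without
resistance or external force).

The re-integration check — integrating the chain forward under the
inverse-dynamics torques and recovering the measured angles — needs care.
Around upright postures the chain is an unstable inverted pendulum stack:
its linearization has modes growing at roughly 4–10 s$^{-1}$ (the HAT
segment's gravitational stiffness is ~135 N m/rad with no lumbar viscous
term; the short pelvis segment is worse), so any discretized torque
representation has its error amplified by $10^5$–$10^{13}$ over 3 s. An
open-loop residual there measures conditioning, not correctness. The
package therefore verifies (i) the implied accelerations against the true
accelerations on STS kinematics at $10^{-12}$, and (ii) full 3 s
re-integration on a smooth trajectory in the gravitationally *stable*
regime (the chain swung about its hanging equilibrium, lumbar kept within
one resistance branch), where the residual is ~$10^{-8}$ rad against a
$10^{-3}$ rad bound. `forward_simulate_chain()` interpolates torques with
cubic splines and integrates at $10^{-11}$ tolerance for the same reason.

## Hill-type muscle model

Eleven uni- and bi-articular muscles (TA, SOL, GAS, RF, VAS, BFL, BFS,
GMAX, RA, ES, IL) produce tension $F = F^{CE} + F^{PE}$ with

$$F^{CE} = F^{\max} f_{fl}(\hat l)\, f_{fv}(\hat v)\, \hat m, \qquad
  f_{fl} = e^{-(\hat l - 1)^2}, \qquad f_{fv} = 1 + \tanh(3 \hat v),$$

and a passive element that is zero below optimal fiber length, rises as
$F^{\max} e^{10(\hat l - 1)}/e^5$ up to $\hat l = 1.5$ (where it equals
$F^{\max}$ exactly, continuously) and saturates beyond. Positive $\hat v$
means shortening, so $f_{fv} > 1$ concentrically — conventions vary across
the Hill literature, so this is stated once here and asserted in tests.
Pennation, tendon elasticity and activation dynamics are deliberately not
modeled.

Muscle kinematics use a constant-moment-arm linearization
$l = l_{\mathrm{ref}} - \sum_k r_k (\theta_k - \theta_{\mathrm{ref},k})$
about the upright reference posture: no muscle-path geometry is assumed
beyond the moment arms themselves, which already parameterize the
torque mapping $\tau_k = \sum_i r_{ki} F_i$. Default $F^{\max}$, optimal
fiber lengths, contraction-velocity limits and signed moment arms are
literature-order values shipped in `muscles.yaml`; every entry is
overridable, and the moment-arm signs were cross-checked against the
static-balance oracle (extensors must supply the torque gravity demands
in a forward-leaning posture).

IL (iliopsoas) is a deep hip flexor with no surface-EMG channel. Its
activation is modeled as a fixed bell-shaped profile over the hip-flexion
phase (`il_template()`, peak at 35% progress) whose amplitude is a free
bounded variable of the optimizer, and it is excluded from all accuracy
metrics.

## Torque-matching normalization

For measured envelopes $e_i(t)$ the normalized activation is constrained to
$\hat m_i(t) = \alpha_i e_i(t)$ with $\alpha_i > 0$: a pure positive
rescaling. This is the strongest reading of a "perfect positive
correlation" constraint — Pearson $r = 1$ with zero intercept — and it
preserves resting baselines and every on/off timing exactly (an affine
variant would also give $r = 1$ but would shift resting activity, so it is
not offered). The scales minimize

$$Z = \lVert T^{\max} - \tau^{\max} \rVert^2
    + \lVert T^{\min} - \tau^{\min} \rVert^2,$$

the squared Euclidean distance between the per-joint torque extrema of the
inverse-dynamics and simulated series over the 3 s window, subject to
$0 \le \alpha_i e_i(t) \le 1$. Because active torque is linear in
activation at fixed kinematics, the simulated torques are affine in
$\alpha$ and the objective is cheap to evaluate from precomputed gains.

With 11 unknowns and 8 extremum equations the problem can be
under-determined; a tiny regularizer $\varepsilon \lVert \alpha - 1
\rVert^2$ ($\varepsilon = 10^{-9}$) makes the reported scales reproducible
without influencing the fit at any practical precision. The solver is
deterministic: a fixed lattice of feasible starts (global multiples of 1
plus eight seeded log-uniform draws) refined by box-constrained
quasi-Newton descent in $\log \alpha$, a Nelder–Mead polish of the best
start, ties broken by the smallest $\lVert \alpha \rVert$. Clipped
activations and infeasible bounds always emit warnings — they are the
method's genuine failure modes, not noise.

The conventional static-optimization baseline
(`static_optimization_baseline()`) minimizes $\sum_i m_i^2$ per time step
under the four joint-torque equalities and box bounds — a quadratic program
per sample, with a bounded least-squares fallback (flagged) for infeasible
steps. On synthetic trials whose ground-truth activations are not of
minimal norm, its per-muscle correlation with the truth falls well below 1,
while the torque-matching method's correlation is 1 by construction; the
test suite asserts this dominance rather than any particular margin.

## Signal conditioning

EMG: zero-lag 4th-order Butterworth band-pass 40–400 Hz, rectification,
zero-lag 4th-order low-pass at 4 Hz. "Zero-lag 4th order" is read as a
2nd-order design applied forward-backward, the standard EMG convention.
Forces: zero-lag low-pass at 20 Hz (order chosen to match the EMG
convention, as none is prescribed). The forward-backward filters are
wrapped with odd-reflection padding sized by the slowest filter pole, so
constant inputs pass with unit gain to $10^{-6}$ and edges carry no
start-up transient. At a 1000 Hz EMG rate the 400 Hz edge sits at 0.8
Nyquist; this is permitted with a warning.

Seat-off is the first sample of the filtered hip vertical force strictly
below 10 N, guarded by a requirement that the first 0.2 s be loaded. One
trial is the window from 1 s before seat-off to 2 s after, resampled to a
common 100 Hz grid (301 samples; the kinematics' native rate, which drives
inverse dynamics) with a 101-point motion-progress copy (0–100%). In
reference mode, envelopes are divided by per-muscle MVC values; the peak
used for comparisons can come from the trial window (default) or the full
recording.

## Synergies and longitudinal statistics

Muscle synergies factorize the activation matrix $M \approx W C$
(muscles × time) by non-negative matrix factorization with Lee–Seung
multiplicative updates on the Frobenius objective: 20 random restarts from
a fixed seed, at most 2000 iterations, relative tolerance $10^{-6}$, the
best restart kept (ties by seed order). Columns of $W$ are rescaled to
unit maximum with the inverse absorbed into $C$, so spatial patterns are
comparable across trials and temporal amplitudes carry the activation
level. Reconstruction quality is the global Frobenius
variance-accounted-for, $100(1 - \lVert M - WC \rVert_F^2 / \lVert M
\rVert_F^2)$ — the formula behind the common 90% adequacy threshold is not
standardized, so the package defines it explicitly. Four synergies are the
default, matching the four STS phases (lumbar flexion, hip raise, body
extension, posture control); extracted synergies are ordered against
phase-labeled spatial templates (RA-, TA-, VAS/ES- and SOL-dominant) by
greedy cosine matching, since trial-by-trial extraction returns them in
arbitrary order.

Per-trial features — each muscle's maximum tension, each synergy's temporal
peak level and peak time — are aggregated per measurement day as
distributions. Between-day change uses the Wilcoxon rank-sum test for two
days and the Kruskal–Wallis test for three or more, with percent change
computed on the per-day means of per-trial maxima; significance is flagged
at $p < 0.001$ for tension features and $p < 0.05$ for synergy features.
The aggregation (per-trial features, per-day distributions) is this
package's declared choice.

## The synthetic generator

`gen_trial()` produces fully self-consistent trials with known ground
truth, which is what makes every pipeline stage testable without any
recorded data:

* minimum-jerk quintic joint trajectories from sit to stand (closed-form
  derivatives, so differentiation error never enters oracle tests), with a
  flexion-then-extension lumbar bump;
* four Gaussian temporal synergy bumps (15/40/65/85% progress) mixed by the
  phase-labeled spatial templates, clipped to [0, 1];
* ground-truth torques defined as the Hill-model torques at the true
  activations — the quantity the optimizer reproduces exactly
  ($Z < 10^{-10}$) at the true scales;
* a quintic seat-unloading force crossing the 10 N threshold exactly at
  the configured seat-off, with the feet carrying the quasi-static
  remainder of body weight (vertical balance holds to 2%; full dynamic
  consistency of the reaction forces is deliberately not imposed — the
  re-integration property has its own dedicated construction);
* raw EMG synthesized as the true envelope modulating a
  rectification-compensated 120 Hz carrier inside the pass band, with
  multiplicative noise (5% default), so preprocessing recovers the
  envelope to well under 1%.

What the generator does *not* emulate: genuine interference-pattern EMG,
motion-capture marker noise, dynamically consistent ground reaction forces,
foot asymmetry, or model mismatch between the subject and the generic
anthropometry. Green tests therefore demonstrate internal consistency and
algorithmic correctness, not clinical validity on recorded patients.

Longitudinal series apply per-synergy amplitude growth (geometric across
days) with per-trial lognormal jitter (10%). Growth-recovery studies use a
low-amplitude baseline configuration (synergy levels ~0.3–0.4): normalized
activation saturates at 1 by definition, so a doubling is only observable
below saturation — which is also the clinically relevant regime, where
patients grow from weak baselines.

## Problem sizes and numerical choices

Test and acceptance runs use one 3 s trial at native rates (2000 Hz
EMG/forces, 100 Hz kinematics, 301-sample window), 20 trials for synergy
reconstruction, 10 trials/day for the growth comparison and 50 seeded
replicates of 2 × 5 trials for the null calibration; static optimization
and some optimizer tests subsample to 101 frames. These sizes were chosen
so each check isolates one property at full numerical fidelity.

Other deliberate numerical choices: envelopes are clipped at zero after
filtering (Butterworth undershoot); normalized muscle length is clamped
above 0.1 with a warning; synergy ties take the first index; zero-variance
series yield `NA` correlations with a warning rather than an error; the
percent-change baseline of zero is an error, not `Inf`.
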