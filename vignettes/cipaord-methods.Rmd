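---
title: "Methods: model, metrics and numerics in cipaord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model, metrics and numerics in cipaord}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical design of
**cipaord**: the cell model and its conductance scaling, the IKr Markov
chain with dynamic drug binding, the metric definitions, the risk
classifier, the robustness analysis, the calibration procedure, and the
provenance of the shipped fixtures.

## Cell model and conductance scaling

The base model is the O'Hara–Rudy dynamic (ORd) human endocardial
ventricular myocyte (O'Hara et al. 2011): 39 Hodgkin–Huxley gates and
concentration states plus, in this implementation, 7 IKr Markov
occupancies, for 46 state variables in units of ms, mV, mM and µA/µF with
outward current positive. The right-hand side is compiled C
(`src/ord_model.c`) registered for `deSolve::lsoda` with
`rtol = atol = 1e-6`.

Five conductance scalers multiply IKr, IKs, IK1, ICaL and INaL. Two named
settings are provided:

- `scaling_original()`: IKr ×0.9, all others ×1 (the rescaling introduced
  when IKr is converted from its Hodgkin–Huxley to its Markov form);
- `scaling_optimized()`: IKr ×1.013, IKs ×1.870, IK1 ×1.698, ICaL ×1.007,
  INaL ×2.661 — the calibrated setting used by default. The INaL scaler
  corresponds to a 166.1 % increase over baseline.

## IKr Markov chain and dynamic drug binding

The drug-free wing is a 2×2 ladder — closed/open × non-inactivated/
inactivated (`c`, `o`, `i`, `ci`) — constructed so that its open
occupancy reproduces the base ORd IKr gating exactly: horizontal
(activation) transitions use the ORd steady state
$x_{r,\infty}(V) = 1/(1+e^{-(V+8.337)/6.789})$ with the effective time
constant $\tau_{xr} = A_{xr,f}\tau_{xr,f} + (1-A_{xr,f})\tau_{xr,s}$, and
vertical (rectification) transitions relax to the ORd rectification gate
$r_{Kr}(V)$ with a fast time constant of 2 ms. With no drug present the
paced model is therefore bit-for-bit equivalent in current to the
Hodgkin–Huxley formulation it replaces, which lets control steady states
be validated independently of the pharmacology.

Drug at concentration $D$ binds the open and inactivated conformations
only, at

$$K_b = K_{max} \, K_u \frac{D^n}{D^n + \text{halfmax}},$$

so block is use dependent: closed channels at rest cannot bind. Bound
channels keep gating — `ob` deactivates into a closed-bound state `cb`
with the activation rates and exchanges with `ib` at the rectification
rates. Unbinding proceeds at $K_u$ from `ob`/`ib`; escape from the
trapped state `cb` is additionally voltage gated,

$$k_{untrap}(V) = \frac{K_u}{1 + e^{-(V - V_{half})/6.789}},$$

so a drug with a depolarized $V_{half}$ remains trapped in closed
channels throughout diastole (dofetilide-like behavior), while a
hyperpolarized $V_{half}$ lets the drug dissociate between beats
(verapamil-like behavior). Binding changes only occupancies; the current
is always $I_{Kr} = 0.046\, s_{Kr} \sqrt{[K]_o/5.4}\; O \,(V - E_K)$
with $O$ the drug-free open-state occupancy.

Two properties are enforced and tested:

- occupancy conservation: the seven occupancies sum to 1 to within
  $10^{-6}$ along paced trajectories; drift beyond $10^{-8}$ between
  beats is renormalized with a logged warning;
- trapping asymmetry: at identical equilibrium affinity, a
  slow-unbinding trapped parameterization retains strictly more bound
  channel through a diastolic hold than a fast-unbinding untrapped one.

An earlier design in which the bound wing was frozen (no gating, constant
escape) could not produce this asymmetry — fast unbinding implied faster
binding through $K_b \propto K_u$ with nothing lost during diastole — and
was replaced by the gated-wing topology above.

## Pacing, recording and arrhythmia detection

Each beat applies a −80 µA/µF, 0.5 ms stimulus; integration is split into
a stimulus and a post-stimulus segment. Beats are recorded on a grid of
0.01 ms for the first 20 ms (upstroke) and 1 ms thereafter. Control
steady state is 1000 beats from model initial conditions; end-of-run
states for cycle lengths 1000, 2000 and 4000 ms ship as plain-text
snapshots (`inst/extdata/steady_state_cl*.csv`) that
`control_steady_state()` tops up with two beats, making the test suite
and the acceptance script independent of the 1000-beat transient.

EADs are detected as a positive voltage slope sustained over at least two
consecutive recording intervals inside a configurable window (plateau,
APD30–APD90, or the full repolarization); a beat with no elicited action
potential returns `NA` rather than a spurious detection. Alternans is a
beat-to-beat APD90 difference above 5 ms.

## Metrics

`qnet()` integrates the sum ICaL + INaL + IKr + IKs + IK1 + Ito by the
trapezoid rule over one beat and divides by 1000 (µC/µF). Per-current
charges use the same rule, so qNet equals the sum of the six per-current
charges to within $10^{-4}$. `cq_inward()` is the mean of the
drug-to-control charge ratios of INaL and ICaL. `metric_panel()` gathers
these together with AP morphology (APD50/90, triangulation, dV/dt max)
and calcium transient measures, and flags conditions whose steady beat
shows an EAD, alternans or failed repolarization as invalid; downstream,
invalid doses inherit the metrics of the highest valid lower dose.

## Risk classification

`fit_risk_model()` fits a cumulative-logit (proportional-odds) model of
the three TdP risk levels on a standardized metric, with a small ridge
penalty (λ = 10⁻³) on the slope for stability on separable data, by BFGS
on the parameterization (ζ₁, log(ζ₂−ζ₁), β). Prediction is the
category of maximal probability with ties resolved to the lower level.
Training and leave-one-out errors are the mean absolute difference
between predicted and assigned levels. The unit tests cross-check the
fit against `MASS::polr` and against a brute-force two-cutpoint
classifier oracle.

## Robustness analysis

`ikr_reduction_threshold()` finds the minimal additional IKr conductance
reduction (in percent, up to 99.99) that triggers an EAD within 100 beats
started from the drugged steady state, by bracketed binary search to a
configurable precision; the generic search is validated against a linear
scan on synthetic predicates. A condition already showing EADs reports
status `"zero"`, and one without EADs even at maximal reduction reports
`"not_found"`; both are excluded from `metric_threshold_correlation()`,
which requires at least three valid pairs.

## Calibration

`optimize_conductances()` recovers the five scalers from APD targets under
channel-block conditions (70 % IKr block, 90 % IKs/ICaL/IK1 block, and a
mexiletine-like mixed block) by an elitist rand/1/bin differential
evolution with Latin-hypercube initialization (plus an all-ones member),
bounds [0.001, 9], weights 1/SD², and convergence when the best cost
improves by less than 5 % over 30 generations. The objective is
injectable, so recovery is exercised cheaply against surrogate response
surfaces in the tests and the acceptance script, with the full simulated
objective available for real calibrations.

## Fixtures and their provenance

All fixtures are plain text. The drug panel
(`inst/extdata/fixture_drug_*.csv`) is a synthetic 12-compound training
set anchored to published CiPA values (Li et al. 2017; Dutta et al.
2017; Crumb et al. 2016): per-channel IC50/Hill constants and free Cmax
follow the published functional-assay ranges, and the IKr binding rows
are constructed under a fixed rule — $K_{max} = 10^6$,
$\text{halfmax} = K_{max}\,\mathrm{IC50}^{\,n}$ (so the bound/free
equilibrium ratio is $(D/\mathrm{IC50})^n$), with $K_u$ and $V_{half}$
set per kinetic class (trapped, intermediate, fast-unbinding). These
parameters were fixed before any downstream quantity was computed and
are not tuned to outcomes.

## Numerical choices and limitations

- `lsoda` with `rtol = atol = 1e-6` balances speed (≈8–10 ms of CPU per
  beat) against metric stability; qNet is reproducible to well under 1 %
  at these tolerances.
- Markov renormalization warnings at very long cycle lengths (4000 ms)
  reflect drift marginally above the 10⁻⁸ threshold and are expected.
- The binding-rate construction reproduces equilibrium block exactly but
  only approximates published kinetics; quantitative agreement of
  worked examples is therefore within, not at, the reported values.
- Only the endocardial cell type is implemented.

## References

- O'Hara T, Virág L, Varró A, Rudy Y (2011). Simulation of the
  undiseased human cardiac ventricular action potential. PLoS Comput
  Biol 7:e1002061.
- Li Z, Dutta S, Sheng J, et al. (2017). Improving the in silico
  assessment of proarrhythmia risk by combining hERG channel–drug
  binding kinetics and multichannel pharmacology. Circ Arrhythm
  Electrophysiol 10:e004628.
- Dutta S, Chang KC, Beattie KA, et al. (2017). Optimization of an in
  silico cardiac cell model for proarrhythmia risk assessment. Front
  Physiol 8:616.
- Crumb WJ, Vicente J, Johannesen L, Strauss DG (2016). An evaluation of
  30 clinical drugs against the CiPA proposed ion channel panel.
  J Pharmacol Toxicol Methods 81:251–262.
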