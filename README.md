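# cipaord

Drug proarrhythmia assessment with an optimized O'Hara–Rudy human
ventricular myocyte model, following the Comprehensive in vitro
Proarrhythmia Assay (CiPA) paradigm (O'Hara et al. 2011; Li et al. 2017;
Dutta et al. 2017).

The package simulates the endocardial action potential with a compiled-C
right-hand side under `deSolve::lsoda`, represents the rapid delayed
rectifier current IKr as a seven-state Markov chain with state-dependent
drug binding and closed-state trapping, blocks six further currents with
Hill equations, and derives torsade-de-pointes (TdP) risk metrics from the
paced steady state.

## What it computes

- **Model core** — the full O'Hara–Rudy dynamic endocardial cell (46 state
  variables) with five ionic conductance scalers. The optimized scaling
  (`scaling_optimized()`) multiplies IKr ×1.013, IKs ×1.870, IK1 ×1.698,
  ICaL ×1.007 and INaL ×2.661 relative to the base model.
- **IKr dynamic drug binding** — drug binds the open and inactivated
  channel, bound channels keep gating, and escape from the closed-bound
  state is voltage gated, so depolarized-midpoint drugs stay trapped
  through diastole (`markov_transition_rates()`, `markov_stationary()`).
- **Pacing engine** — stimulus delivery, steady-state pacing with Markov
  renormalization, EAD and alternans detection (`pace_to_steady_state()`,
  `detect_ead()`).
- **Metrics** — qNet (the net charge of the six principal plateau
  currents), per-current charges, APD50/APD90, triangulation, calcium
  transient measures and cqInward, assembled by `metric_panel()`.
- **Risk classification** — a ridge-penalized proportional-odds
  (cumulative logit) model over three TdP risk levels with training and
  leave-one-out error (`fit_risk_model()`, `risk_loo_error()`).
- **Repolarization robustness** — the minimal additional IKr conductance
  reduction that triggers an EAD, found by bracketed binary search, and
  its correlation with candidate metrics (`ikr_reduction_threshold()`).
- **Calibration** — differential-evolution recovery of the five scalers
  against APD rate-dependence targets (`optimize_conductances()`).
- **CLI and IO** — `inst/cli/cipaord.R` exposes `simulate`, `classify`,
  `threshold` and `calibrate` subcommands; result CSVs carry provenance
  headers (package version, configuration hash, seed).

A 12-compound panel (high/intermediate/low TdP risk training set) ships as
plain-text fixtures under `inst/extdata/`, with per-channel Hill
parameters, IKr binding kinetics and free Cmax values.

## Quick start

```r
library(cipaord)

## control steady state at cycle length 2000 ms (snapshot + top-up beats)
ctrl <- control_steady_state(2000)
beat <- ctrl$beats[[length(ctrl$beats)]]
apd(beat, 0.9)   # ~307.2 ms
qnet(beat)       # ~0.0639 uC/uF

## ranolazine at 25x free Cmax
drugs <- fixture_drug_panel()
row <- simulate_drug_condition(drugs$ranolazine, 25, cl = 2000,
                               control = ctrl)
row$qNet         # ~0.058 uC/uF
row$APD90        # prolonged vs control

## minimal IKr reduction that triggers an EAD under dofetilide at 1x
p <- apply_drug(ord_params(), drugs$dofetilide, 1)
ss <- pace_to_steady_state(ctrl$state, p,
                           pacing_protocol(cl = 2000, n_beats = 500))
ikr_reduction_threshold(p, ss$state, cl = 2000, precision = 0.5)
```

## Command line

```sh
Rscript inst/cli/cipaord.R simulate --drug dofetilide --dose 25 \
  --variant optimized-dynamic --out results.csv
Rscript inst/cli/cipaord.R classify --metric qNet --dose 10 --out risk.csv
```

## Reproduction

```sh
R CMD INSTALL --no-docs .
Rscript -e 'testthat::test_dir("tests/testthat")'
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

`scripts/acceptance.R` recomputes the headline quantities (control and
drugged qNet, charge and APD changes at 25× Cmax, classification
training/LOO errors, robustness threshold statuses and correlations, the
dofetilide safety margin, and seeded calibration recovery) and writes them
as JSON. The steady-state snapshots in `inst/extdata/` can be regenerated
from a cold start with `tools/make_steady_fixtures.R`.

See the vignette (`vignettes/cipaord-methods.Rmd`) for the model
equations, the IKr binding topology, fixture provenance and numerical
choices.
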