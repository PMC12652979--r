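---
title: "Modeling the ER stress decision between autophagy and apoptosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the ER stress decision between autophagy and apoptosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erswitch)
```

## The model

When misfolded proteins accumulate in the endoplasmic reticulum, the
unfolded protein response (UPR) decides between two mutually exclusive cell
fates: autophagy-dependent survival and apoptotic death. `erswitch`
implements a deliberately coarse-grained ODE model of that decision with
five lumped state variables, each an activity in arbitrary units (a.u.):

* `upr` — one UPR sensor standing in for the IRE1/PERK/ATF6 branches
  together;
* `bcl2` — active anti-apoptotic BCL-2, the hub that holds both effector
  arms off;
* `aut_a` — the active autophagy-inducer group (Beclin-1-like activities);
* `aut_i` — its caspase-cleaved, inactive fragment;
* `apo_a` — the active apoptosis-inducer group (caspase-like activities).

The wiring is: ER stress activates `upr`; `upr` inactivates `bcl2`; `bcl2`
suppresses activation of both `aut_a` and `apo_a`; `aut_a` and `apo_a`
antagonize each other (the arm from `apo_a` to `aut_a` is realized as
caspase-dependent cleavage producing `aut_i`); `aut_i` feeds back positively
on `apo_a` activation; and `apo_a` cleaves `bcl2`. The double-negative
loops make the system a bistable switch; the `aut_i` arm adds a
self-amplifying commitment loop for death.

Each variable obeys a production-minus-consumption kinetic equation.
Switch-forming interactions use saturating Michaelis–Menten
activation/inactivation terms — with small Michaelis constants these run in
the zero-order-ultrasensitive regime, which is what generates sharp,
bistable transitions. Cleavage reactions are mass action. The autophagy
pool is conserved by construction: `aut_a + aut_i + (uncleaved inactive
fraction) = AUT_T` along every trajectory, since that pool is only moved by
activation, inactivation, cleavage and fragment turnover. For numerical
robustness the activation term is clamped to zero if the integrator ever
overdraws the pool; inside the admissible box the right-hand side is
continuously differentiable and the analytic Jacobian (`ers_jacobian()`)
is exact.

## Stressor inputs

The three common chemical stressors enter the model according to their
known points of attack:

* **Tunicamycin (TM)** blocks N-glycosylation and acts purely upstream:
  "TM at dose s" is simply `stress = s`; there is no separate TM input.
* **Thapsigargin (TG)** additionally activates both effector arms
  directly: `tg` adds activation terms on `aut_a` and `apo_a`.
* **Dithiothreitol (DTT)** additionally activates the apoptosis arm only
  (`dtt`). No dose for this direct action is established, so the package
  default (`dtt = 0.25` in the `dtt_low` scenario) is calibrated such that
  even low-stress DTT abolishes the survival window; the scenario is
  flagged as model-extrapolated in the registry.
* **Autophagy inducers** (resveratrol-like compounds) multiply the
  `aut_a` activation rate constant by `kaua_mult`. Treatments are defined
  by the absolute treated rate 10 a.u./time, i.e.
  `kaua_mult = 10 / kaua_base`, so the same scenario definition works for
  any parameter variant.

## The calibrated parameter set

No community-standard parameterization exists for this lumped model, so
the package pins its own (`canonical_parameters()`, schema-versioned, also
shipped as `inst/extdata/calibrated_default.yaml`). Totals are normalized
to 1 a.u.; rate constants are per relative time unit; Michaelis constants
are dimensionless. The set was calibrated once (procedure in
`tools/calibration.R`) to meet all of the following at the same time:

* at `stress = 0`: two stable states — a physiological state with basal
  autophagy (`aut_a` ≈ 0.07) and apoptosis off, and an apoptotic state —
  separated by a saddle;
* `stress = 5`: sustained autophagy (`aut_a` ≈ 0.76) from the
  physiological state;
* `stress = 50`: a pronounced transient autophagy peak (≈ 0.84 a.u. near
  t ≈ 6) followed by commitment to apoptosis;
* `stress = 5, tg = 0.25`: a single stable state, apoptotic;
* inducer at absolute rate 10: the survival fold moves from ≈ 42 to ≈ 62,
  so high TM is rescuable while high TG is not.

Two calibration choices deserve comment. First, the decisive lever for
rescue is the position of the autophagy arm's collapse threshold in
`apo_a`: the inducer multiplies the activation rate ~20-fold, which moves
that threshold out of reach of the slowly creeping apoptosis activity.
Second, the apoptosis equation is uniformly slower than the other arms
(all its rate constants share a factor 0.3 relative to an earlier draft of
the set). A uniform scaling of one equation leaves every equilibrium and
fold untouched but separates timescales, so trajectories track the
survival branch up to the fold — giving the clean hysteresis, the
transient autophagy phase under high stress, and finite rescue/washout
windows.

## Analyses

**Simulation** (`simulate_model()`) integrates piecewise between treatment
events with `deSolve::lsoda` and the analytic Jacobian (tolerances
`rtol = 1e-8`, `atol = 1e-10`; at least 500 output points per segment).
Events are step changes of the input fields; integration restarts at each
event so discontinuities never fall inside a solver step, and the state is
continuous across events.

**Outcome classification** (`classify_outcome()`) is deliberately simple:
a trajectory is apoptotic if `apo_a` exceeds its threshold over the entire
final 10% of the horizon, else autophagic if `aut_a` does, else
homeostatic. Thresholds default to half the respective total; because the
attracting states are near fully-on/off, any threshold in 0.4–0.6 of the
total gives the same labels on the canonical scenarios (asserted in the
tests). A "transient peak" (`detect_transient_peak()`) is a global maximum
that the trace later undercuts by 75% — the 25% fall-off fraction is a
package convention; the observed behavior is not sensitive to it.

**Steady states** (`find_equilibria()`) are located by multi-start damped
Newton iteration: a 3-per-axis grid over the (bcl2, aut_a, apo_a) box plus
seeded random starts (81 by default), duplicate-merged at `1e-6`, refined
to residual `1e-10` and classified through the Jacobian eigenvalues with
hyperbolicity margin `1e-9`. Saturation with respect to the number of
starts is a tested property, and a `marginal` classification is treated as
a failure by downstream analyses rather than silently accepted. A
dedicated root finder (rather than a library steady-state solver) keeps
the refinement under the package's control; long-horizon integration
serves as the independent check in the tests.

**Balance curves** (`nullclines()`) reduce the model to the
(`aut_a`, `apo_a`) plane by solving the other three variables to steady
state per grid point — numerically, so the reduction stays valid for any
kinetic form — and extract the zero contours of the two reduced rates on a
shared grid, refining every polyline vertex by one-dimensional
root-finding to residual `1e-6`. Crossings are found by segment-pair
intersection and must agree with the equilibrium projections to `1e-3`
(tested at five stress levels).

**Bifurcation diagrams** (`continue_in_stress()`) use pseudo-arclength
continuation (secant predictor, Newton corrector on the bordered system,
adaptive step halving between `1e-5` and `1.0`) seeded from both ends of
the scan range, so saddle-node folds are traversed, detected by reversal
of the stress progression, and refined to `1e-4`. The multi-start root
finder run independently at sampled stress values is the module's oracle.
One structural point: because the network is already bistable at
`stress = 0` (the washout experiments require the apoptotic state to be
stable without stress), the lower saddle-node of the S-shaped response lies
at negative — unphysical — stress. A scan over the physical range
therefore contains exactly one fold, the survival-branch limit point at
stress ≈ 42; the bistable interval is reported as [0, fold].

**Scans and ensembles.** `rescue_window_scan()` and `washout_scan()`
classify outcomes over a grid of intervention times and refine the
success/failure boundary by bisection to 0.01 time units; both error
loudly if the success pattern is non-monotone, since a single threshold is
the assumed structure. The pre-treatment lead time defaults to 20 a.u.
`perturbation_ensemble()` multiplies every rate constant by independent
log-normal factors (median 1, given CV), re-runs the low-TM/high-TM/low-TG
outcome triplet per draw and reports the fraction of draws preserving all
three labels; identical seeds give identical ensembles.

## What the scenarios do and do not emulate

The scenario registry (`standard_scenarios()`) stands in for experimental
treatment protocols: doses are the model's dimensionless input levels, and
times are in arbitrary units — there is no mapping to hours or to
micromolar concentrations of any real compound. Passing tests therefore
show that the *wiring logic* reproduces the qualitative fate map
(dose-dependent TM outcomes, TG/DTT lethality at low dose, additivity,
finite rescue and washout windows, irreversibility), not that the model is
quantitatively predictive for any cell line. Absolute onset times and
threshold values depend on the calibrated set and should only be read as
orderings.

## Numerical choices and degenerate inputs

* Integration tolerances `1e-8`/`1e-10`; halving them moves canonical
  endpoints by less than `1e-5` (tested).
* Newton refinement accepts a root only inside the admissible box (within
  `1e-6`) and at residual below `1e-10`; with pathological parameters an
  empty equilibrium list plus a warning is returned, never an exception.
* A washout at time 0 is the degenerate "never stressed" case and is
  classified as homeostasis without simulation.
* `classify_outcome()` refuses horizons shorter than 10 time units after
  the last event.
* The ensemble redraws (and counts) parameter sets that violate
  positivity; with CV ≤ 0.5 this is rare.

## Known limitations

* The five-variable lumping cannot resolve branch-specific UPR biology
  (IRE1 vs PERK vs ATF6), and BAX appears only folded into the BCL-2
  inhibition of the apoptosis arm, not as a dynamic variable.
* The robustness fraction at CV = 0.1 is moderate (the switch thresholds
  sit where joint perturbation of all 25 rate constants can move outcomes
  across the dose landmarks at 5 and 50); the ensemble report quantifies
  this rather than hiding it.
* Stochastic effects, spatial structure and protein identity are out of
  scope by design.

## A worked example

```{r example, eval = FALSE}
params <- canonical_parameters()

# high-dose tunicamycin: transient autophagy, then death
traj <- simulate_model(params,
                       treatment_schedule(ers_input(stress = 50),
                                          t_end = 250))
classify_outcome(traj)
#> <ers_outcome> apoptosis (onset t=50.10) | AUT-A peak 0.842 @ t=6.41

# the switch structure behind it
continue_in_stress(params, ers_input(), stress_range = c(0, 60))
#> <ers_bifdiag> 4 branch(es) over stress [0, 60]
#> limit points at stress: 41.8356
#> bistable interval: [0.0000, 41.8000]
```
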