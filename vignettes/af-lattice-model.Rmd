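---
title: "An anisotropic excitable-lattice model of atrial fibrillation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An anisotropic excitable-lattice model of atrial fibrillation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aflattice)
```

## The model

Atrial muscle is organised as branching cables: myocytes (roughly 100 um
long and 20 um across) couple strongly end to end and only sparsely side
to side, and fibrosis — which accumulates with age — erodes the
side-to-side coupling further. `aflattice` implements a deliberately
minimal model of activation on that architecture and of how atrial
fibrillation (AF) emerges from it.

The tissue is an `L x L` lattice of cells forming `L` horizontal cables.
Longitudinal couplings are always present (open boundaries left and
right); each of the `L^2` candidate transverse edges between vertically
adjacent cells exists independently with probability `nu`, and the
lattice wraps periodically in the transverse direction (a cylinder, the
topological skeleton of an atrium). A fraction `delta` of cells is
*dysfunctional*. The substrate — edges, dysfunction mask, ablation mask —
is drawn once from a seed and then fixed; all ageing- or fibrosis-related
change is summarised by lowering `nu`.

Each cell is resting, excited, or refractory. The synchronous update
rule, all reads from the pre-update state:

* a resting, non-ablated cell with at least one *coupled* excited
  neighbour becomes excited — unless it is dysfunctional, in which case
  it fails with probability `epsilon` (one Bernoulli trial per
  stimulated cell per step, however many excited neighbours it has,
  drawn in row-major order so runs are reproducible);
* an excited cell is excited for exactly one step and then refractory
  for exactly `tau` steps, so an excitation makes the cell unexcitable
  for `tau + 1` consecutive steps;
* the left boundary column is the pacemaker: whenever the pre-update
  time is a multiple of `T`, its resting cells self-excite
  unconditionally (a refractory pacemaker cell skips that beat).

Excitation propagates in every coupled direction, including retrograde;
there is no imposed directionality and no update-order ambiguity.

The refractory accounting deserves one sentence, because two
conventions circulate for three-state automata: here a cell excited at
`t` can be re-excited at `t + tau + 2` at the earliest. This is the
convention under which the analytic criticality condition below
(`ell >= tau/2` for even `tau`) is reproduced *exactly* by the
dynamics; with the shorter window (`tau` total) the two-cable circuit
already closes at `ell = tau/2 - 1` and the closed-form risk would be
systematically off by one gap cell. The test suite pins this with a
hand-steppable motif at `tau = 4`.

### Physical scale

`physical_params()` carries the tissue values (cell size, 0.6 ms
depolarization step, 150 ms refractory period, 660 ms pacing period,
a sheet of about 20 cm^2) and `model_config_from_physical()` converts
them. The lattice must hold as many cells as the sheet,
`L^2 = L'^2 / (b^2 dx dy)`, where `b` is the coarse-graining factor
(`b` cells merged per lattice unit; times rescale by `b dt` and the
coupling by `nu -> 1 - (1 - nu)^b`, see `coarse_grain_nu()`). The
defaults with `b = 5` give the dimensionless study conditions used
throughout: `L = 200`, `tau = 50`, `T = 220`, `delta = epsilon = 0.05`;
`b = 1` gives `L = 1000`. Note that `L` follows from the cell *area*
`dx * dy`, not from `dx` alone — cells are anisotropic bricks, and only
the area-based conversion reproduces both printed lattice sizes and the
exponent of the dimensional risk formula below.

## Critical regions and the analytic risk

When `nu` is high the paced wave front stays planar. When it is low,
a dysfunctional cell that blocks conduction can seed a *micro-reentrant
circuit* through the simplest two-cable motif: the blocked cable stays
quiet while the neighbouring cable carries the front to the first
transverse connection at distance `ell`, feeds it back retrogradely,
and — if the return path outlasts the refractory period — re-excites
the tissue behind the block, closing a loop of period `2 ell + 4`
steps. The gate condition is `ell >= tau / 2` (ties critical; for odd
`tau` the integer criterion is `ell >= ceiling(tau/2)`).

With `p_nu = 1 - (1 - nu)^2` the probability of a transverse coupling
per cell (`p_transverse()`), `ell` is geometric, and

* `P(ell < tau/2) = 1 - (1 - nu)^tau` (`p_short_circuit()`), and with
  `delta L^2` dysfunctional cells on average,
* `P_risk = 1 - [1 - (1 - nu)^tau]^(delta L^2)` (`p_risk()`; the
  dimensional form is `p_risk_physical()`),
* with point of steepest slope
  `nu* ~ 1 - (delta L^2)^(-1/tau)` (`nu_star()`), about 0.141 under
  the default conditions.

`nu_star()` decreases with increasing `tau`: prolonging refractoriness
(what class-III antiarrhythmic drugs do) shrinks the set of structures
able to sustain reentry without touching the structure itself.

`find_critical_regions()` locates exactly these motifs in a substrate:
dysfunctional, non-ablated cells whose distance to the first
transversely coupled cell at or to their right (`ell_distance()`,
offset 0 on the cell itself) is defined and at least `tau/2`. Cells
with *no* coupled cell before the open right boundary are not critical —
without a transverse edge no loop can close.

### Finite-lattice corrections

`mc_risk_estimate()` draws substrates and reports the fraction
containing at least one critical region. Its target is not quite
`p_risk()`: the closed form assumes independent dysfunctional cells on
an unbounded cable, while the lattice truncates `ell` at the right
boundary and lets several dysfunctional cells share one long uncoupled
corridor, so critical cells arrive in correlated bunches. Both effects
depress the true risk; at the default conditions the deficit peaks
around 0.10 near the transition. `p_risk_finite()` computes the
finite-lattice probability exactly within a cable by dynamic
programming over the distance-to-next-coupling process (cables treated
as independent — the residual correlation through shared edges between
neighbouring cables is negligible against sampling noise at these
sizes; we verified agreement with 1000-substrate Monte Carlo at every
grid point of the transition region). The acceptance checks therefore
compare the Monte Carlo fraction tightly against `p_risk_finite()` and
against `p_risk()` with the analytically computed deficit added — no
fitted constants.

## Classifying fibrillation-like activity

The phase diagram needs an operational definition of "time spent
displaying nonplanar wave fronts", which the underlying description of
the experiment leaves open. The primary metric (`af_activity()`,
`time_in_af()`) thresholds the per-step excited-cell count at
`threshold_factor * L`, strict inequality. A single planar front
excites at most one cell per cable per step (`<= L`); but it is *not*
true that regular rhythm never exceeds `L`: a dysfunctional cell that
fails two consecutive trials is re-excited retrogradely one step behind
the front, and such isolated stragglers push counts a few cells above
`L` (measured maxima 203–208 at `L = 200` for `delta` up to 0.3, with
zero reentrant activity and fully quiescent gaps between beats).
Genuinely nonplanar activity carries at least a second simultaneous
front and runs at several hundred excited cells. The default
`threshold_factor = 1.1` sits between the two regimes; the strict
factor 1 remains available as an argument.

The secondary detector is event-based and parameter-free: a cell
re-excited when *no* pacemaker firing since its previous excitation
could have reached it (a wave needs at least `x - 1` steps to reach
column `x`) must have been excited by circulating activity. The online
form runs inside `run_episode()` (fields `first_reentry`,
`last_reentry`, `n_reentry_events`); `reentry_detector()` recomputes
the same criterion offline from a recorded activation log. Because any
excitation genuinely caused by the newest paced wave arrives no earlier
than that wave possibly can, the detector has no false positives from
slow or detouring sinus conduction; it flags precisely re-excitation by
old, circulating wave fronts.

## Experiments

`phase_sweep()` reproduces the phase diagram: for each `nu` and
realization (substrate seed = base seed + realization index, shared
across `nu` as common random numbers) it records `time_in_af`, the
scanner count and the reentry flag. The package defaults — 5
realizations of 2e4 steps at `L = 200` — are a deliberately scaled-down
protocol chosen so that the full grid runs in a couple of minutes on one
CPU while the transition remains well resolved: with pacing every 220
steps a 2e4-step run offers ~90 independent initiation opportunities,
ample for the bimodal planar/fibrillatory distinction that drives the
mean. The reference protocol (50 realizations of 1e6 steps) is the same
call with different arguments. `transition_estimate()` places the
steepest rise of the mean curve; at the default conditions it lands
within the grid resolution of `nu_star()`.

`ablation_experiment()` closes the loop from scanner to therapy: run
until the online detector sees sustained reentry, scan the substrate,
centre a square lesion (default 20 x 20 — about 1 cm at tissue scale) on
the critical cell nearest the reentry core, and continue.
Lesioned cells are modelled as permanently unexcitable, which subsumes
both "removes excitability" and "removes couplings". The outcome is
judged by the event detector, not by raw excited-cell counts: a paced
front detouring around a fresh lesion transiently recruits the lesion
shadow and can exceed `L` without any circulating activity, so
*terminated* means no reentry event during the final two pacing cycles
of the post-lesion run. `time_in_af` over the tail is reported
alongside for inspection.

The scripted scenario for this experiment is `make_fixture
("critical_one")`: a sparse random background (`nu = 0.14`) with a
single carved two-cable circuit (`ell = 30 >= tau/2 = 25`) whose only
dysfunctional cell is the circuit's gate. The background matters: on a
fully coupled background a 20 x 20 obstacle can itself anchor a rotor
(perimeter ~76 > `tau + 1`), an artifact absent in the sparse regime
the model actually inhabits, where circumnavigating an obstacle would
require long runs of consecutive vertical edges. With `epsilon = 0.05`
the circuit also terminates *itself* with probability `epsilon` per
revolution when the gate cell blocks the retrograde front — the model's
version of paroxysmal, self-terminating AF — so an off-target control
lesion is asserted to leave the circuit firing (reentry events continue
post-lesion), not to guarantee indefinite persistence.

## Fixtures, determinism and degenerate inputs

`make_fixture("toy_circuit")` builds the bare two-cable motif (two
vertical edges, one dysfunctional cell) and
`prepare_wavebreak_state()` constructs the tissue state at the moment
of a conduction block, so the sustain-iff-`ell >= tau/2` property is
tested deterministically with `epsilon = 0` instead of waiting for a 5%
failure; the stochastic initiation path is exercised by the ablation
fixture under a fixed seed.

All randomness flows from the user-visible seed: the substrate draw
uses it directly (edges before dysfunction, so edge topology is shared
across `delta` at a fixed seed), the dynamics stream is seeded from it
plus a fixed documented offset, and Monte Carlo / sweep helpers derive
per-replicate seeds by documented increments. The package never touches
the caller's `.Random.seed`. Degenerate inputs behave as the formulas
dictate: `nu = 0` gives isolated cables (no circuit can ever close, so
the scanner reports no critical regions even though every `ell` is
undefined — outside the closed form's validity, which would say risk 1);
`nu = 1` gives zero risk; `delta = 0` or `epsilon = 0` make conduction
failure impossible and the dynamics provably pacemaker-driven.
Probability arithmetic runs in log space (`log1p`/`expm1`) so exponents
like `delta L^2 = 2000` do not underflow; the closed-form identities are
tested at 1e-12.

## What the tests do and do not show

The synthetic substrates realise exactly the model's assumptions —
Bernoulli edges, Bernoulli dysfunction, a rigid refractory clock, one
pacemaker column. Passing tests validate the implementation and the
internal consistency of the analytics (simulation matches the
finite-lattice theory; the phase transition sits at the predicted
coupling; removing the scanned structure stops reentry). They say
nothing about real atria: no ionic currents, action-potential
morphology, restitution, conduction-velocity heterogeneity, anatomy, or
nonuniform fibrosis fields are represented, and the two-cable motif is
only the simplest reentry structure — longer multi-cable motifs exist
and are not scanned for. The known quantitative limitations within the
model are the finite-size deficit of the closed-form risk (quantified
by `p_risk_finite()`) and the operational freedom in the nonplanar
activity threshold, both discussed above.

## A worked session

```{r worked, eval = FALSE}
cfg <- model_config(nu = 0.12, seed = 3)      # below nu* ~ 0.141
sub <- generate_substrate(cfg)
nrow(find_critical_regions(sub))              # several structures expected

tr <- run_episode(sub, 2e4, detect_reentry = TRUE)
time_in_af(tr, cfg$L)                         # substantial fraction
tr$first_reentry                              # when/where AF initiated

mc_risk_estimate(model_config(nu = 0.14), 400)
plot(risk_curve(seq(0.05, 0.3, by = 0.005), 50, 0.05, 200))
```
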