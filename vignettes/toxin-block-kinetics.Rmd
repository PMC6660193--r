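---
title: "Kinetics, titration and unbinding energetics of peptide-toxin pore block"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetics, titration and unbinding energetics of peptide-toxin pore block}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poreblock)
```

## The system and the model

Charybdotoxin (CTX) and related scorpion alpha-KTX peptides block
voltage-gated K+ channels with 1:1 stoichiometry: a single bound toxin
plugs the outer pore mouth and stops conduction, and unbinding restores
it.  Because the current amplitude reports the bound fraction with high
fidelity, slow macroscopic relaxations of the current carry the binding
kinetics directly.  `poreblock` implements the complete analysis chain
from such recordings (or from synthetic stand-ins) to rate constants,
ion-titration parameters, a four-state state model, and a transition-state
decomposition of unbinding.

All fits that require iteration use damped (Levenberg-Marquardt) least
squares via `minpack.lm`, with relative convergence tolerances of 1e-12
and at most 500 iterations.  Unit conventions are fixed package-wide:
toxin concentrations enter rate equations in uM, dissociation constants
are reported in nM (`K_D = 1000 * k_off / k_on`), external K+ is in mM,
voltages in mV with depolarization positive, and energies in kJ/mol.
The recording temperature is not part of the data files; the default
`phys_constants()` uses 298.15 K (RT/F = 25.693 mV, RT = 2.479 kJ/mol)
and every function accepts an overriding constants bundle.

## Wash-in/wash-out kinetics

For a 1:1 blocker at concentration `[Tx]`, the bound fraction relaxes
mono-exponentially with

* wash-out: `tau_off = 1 / k_off`
* wash-in: `tau_on = 1 / (k_on [Tx] + k_off)`

`fit_monoexponential()` fits `baseline + amplitude * exp(-(t - t0)/tau)`
and `rates_from_on_off()` inverts the two time constants.  The inversion
requires `1/tau_on > 1/tau_off`; equality would imply a zero association
rate and is rejected.

Numerical choices in the exponential fit:

* deterministic starts — baseline from the last decile, amplitude from
  the (running-median smoothed) first sample, tau from the time to cover
  `1 - 1/e` of the excursion;
* a small deterministic multi-start over tau (the heuristic plus
  span/10, span/3 and span), keeping the lowest-RSS fit.  This guards
  against collapse onto the lower tau bound (one sampling interval) when
  the earliest samples are noisy, which otherwise happens for quotient
  series (below);
* tau is bounded to `[dt, 100 * span]`;
* a series whose fitted amplitude is indistinguishable from zero is
  *flagged* (`no_relaxation = TRUE`), not an error.  The flag compares
  the amplitude with 3x its standard error from the fit covariance.  An
  earlier candidate rule — 3x the per-point noise MAD about a constant
  fit — was rejected because it ignores the sample count: a 0.03-deep
  relaxation sampled 1000 times at 0.03 per-point noise is statistically
  unambiguous yet would be discarded.  The MAD rule survives as the
  fallback when no covariance is available (degenerate fits).

## Open-channel relaxations from trace ratios

When block re-equilibrates after a voltage step opens the channels, the
point-by-point quotient of a +toxin trace over its control relaxes
mono-exponentially with

* `tau(V) = 1 / (k_on(V) [Tx] + k_off(V))`
* asymptote `(I_Tx/I_Con)_inf = k_off / (k_on [Tx] + k_off)`

`rates_from_relaxation()` solves this two-equation system algebraically
per voltage; no iteration is involved.  `trace_ratio()` forms the
quotient after masking the earliest samples, until the control current
reaches a guard fraction (default 0.10) of its steady-state magnitude.
The source recordings do not define where ratio fitting begins; the
guard rule is this package's construction, chosen to exclude the
capacitive/early-activation segment where the quotient is ill-defined.
The returned series carries the control magnitude so that quotient fits
can be inverse-variance weighted (`weights = control^2`): dividing by a
small control current inflates the quotient noise by exactly that
factor, and unweighted fits would let the noisy post-guard samples
dominate.

Multi-cell data are reduced in the order average-then-solve
(`average_then_solve()`): time constants and asymptotes are averaged
across cells per voltage (mean +/- SEM) and the rate equations are
solved at the means.  Per-cell solve-then-average is available by
applying `rates_from_relaxation()` row-wise; whether published SEMs
propagate through the equation system or come from per-cell solves is
not documented in the source data, so both routes are exposed with
average-then-solve as the default.

The voltage dependence of either rate is summarized by
`fit_voltage_dependence()` as `k(V) = k(0) exp(z_delta F V / RT)`,
fitted in log-rate space where the model is linear; `z_delta > 0` means
the rate grows with depolarization (a dissociation rate growing e-fold
per ~50 mV corresponds to `z_delta` of about 0.5).

## Potassium titration

External K+ enhances toxin dissociation and antagonizes association.
Both effects follow single-site (Langmuir) saturation.  One canonical
algebraic form is used for every titration curve:

```
value([K]) = at_sat + (at_zero - at_sat) * half_sat / (half_sat + [K])
```

which equals `at_zero` at zero K+ and tends to `at_sat` at saturation;
it is algebraically identical to the equivalent form written with the
`[K]/(half_sat + [K])` occupancy factor.  The printed typography of the
association-rate variant is ambiguous about which limit multiplies the
saturation factor; the definitions of the zero-K+ rates force the form
above, so both the dissociation and association curves share it.

`fit_langmuir()` is unweighted by default (source data are individual
experiments without stated weights); optional `1/value^2` relative
weighting is available.  The half-saturation constant of the
dissociation-enhancement site typically sits near or above the top of a
0-100 mM concentration span, so its relative standard error is large;
fits with `se(half_sat)/half_sat > 1` carry a `poorly_identified` flag
rather than failing.

Derived summaries: `fold_changes()` (ratio of the two limits),
`selectivity_table()` (per-cation K_D ratios against the high-K+
reference and k_off ratios against the high-Na+ control), and
`s1_availability()` — the ratio of the association-side half-saturation
(K_K2, toxin-free channel) to the dissociation-side one (K_K1,
toxin-bound channel), a lower bound on the fraction of time the
outermost filter site is externally accessible while the toxin is bound
(~0.004 with the published constants).  Whether the published "~9 fold"
K_D increase derives from the rate-constant fits (which give ~7.7) or
from the direct K_D titration fit (which gives ~9.6) is ambiguous in the
source; both routes are computed by the package and neither is
hard-coded as the truth.

## The four-state model of tonic inhibition

Closed and open channels bind toxin with constants `K_DC` and
`K_DO(V) = K_DO(0) exp(zFV/RT)`; gating of toxin-free channels follows a
single Boltzmann `Po(V) = 1/(1 + exp(-ZF(V - Vo)/RT))`.  The
steady-state unblocked fraction is

```
U/Umax = 1 / (1 + [Tx]/K_DO(V) * Po + [Tx]/K_DC * (1 - Po))
```

(`unblocked_fraction()`), equivalent to the gating-equilibrium form
`unblocked_fraction_kv()` under `K_V1 = Po/(1 - Po)`; the equivalence is
property-tested on random parameter draws.  Microscopic reversibility
closes the cycle: `kv2_from_cycle()` returns
`K_V2 = K_V1 K_DC / K_DO`, and `gating_shift()` gives the implied
displacement `(RT/ZF) ln(K_DO/K_DC)` of the bound-channel activation
midpoint (about +2.4 mV for the published 10-Na+ constants at Z = 3.5 —
small, which is why a ~35-45 mV separation between the fitted `Vo` and
the G-V midpoint is mechanistically interesting; the package reports
both numbers via `fit_tonic_inhibition()` and `fit_gv()` and does not
adjudicate between the interpretations).

`fit_tonic_inhibition()` fits resting-inhibition points (V <= -60 mV)
and open-channel asymptotes (V >= -30 mV) jointly in one unweighted
least-squares problem, as a single model curve implies; the regime label
is bookkeeping, not a model switch.  How the two limbs were weighted in
the source fits is unstated; equal weights are used.  Data confined to a
single regime cannot separate `K_DC` from `K_DO` and are rejected.
Bounds: dissociation constants in [1e-3, 1e3] nM, valences in [0, 8],
`Vo` in [-150, +50] mV.  Starts are data-driven (K_DC from the most
negative points, K_DO from the most positive, `Vo` from the steepest
gradient) with a deterministic multi-start over `Vo` in {-90, -70, -50}
mV, because on noisy curves the steepest apparent gradient can sit on
the rising open-channel limb.  One genuine identifiability limit is
worth knowing: with a free gating valence, a single 3%-noise curve can
be fitted slightly better by a shallow-Z solution whose resting limb is
partially open, displacing `K_DC`; recovery statements in the test suite
are therefore made on medians over seeds, and fixing `Z`/`Vo` from an
independent G-V fit (supported via `fixed =`) is the recommended
practice on real data.

With the published 10-K+ parameters the model curve is biphasic on
[-100, +60] mV — flat at deeply negative voltages (closed channels,
voltage-independent block), dipping as channels open into a
higher-affinity open state at negative potentials, then relieving as
depolarization accelerates unbinding.  This shape is asserted as a
structural property in the tests.

Slow inactivation (a ~10% current drop at depolarized holding voltages)
is ignored by the model, since toxin binding and slow inactivation are
mutually insensitive in this system; the trace generator can emulate the
amplitude scale factor for robustness checks but the fitted quantities
are ratios, which cancel it.

## Unbinding energetics and the wobbling simulator

Macroscopic unbinding is first order, so `k_off = A0 exp(-dG/RT)`.
`barrier_from_rate()` inverts this with the transition-state-theory
frequency factor `A0 = 6e12 s^-1` by default (transmission coefficient
1); rates of 3.3 and 0.0061 s^-1 correspond to barriers of about 70 and
85 kJ/mol.  If the interaction surface is a set of `n` independent,
energy-additive contacts, the barrier partitions as `dG = sum(dG_i)` and
the compound constant is the product of per-contact equilibria:
`composite_koff()` returns
`A0 * prod(K_i) * exp(sum(z_j) F V / RT)`.  With 10 energetically
identical contacts, each carries ~2.8-3.5 kT and is unbound ~3-6% of the
time (`per_contact_energy()`).  Voltage acts on designated contacts
through the *rebinding* rate (`local_on * exp(-zFV/RT)`, leaving the
local dissociation rate voltage-independent), the mechanistically
preferred reading for a pore-facing contact competing with permeant
ions; the alternative assignment to the local off-rate is available
behind `voltage_mode = "unbinding"` for sensitivity analysis.

`simulate_contact_network()` is a continuous-time Markov (Gillespie)
simulation over the `2^n` contact configurations with an absorbing exit
taken at the escape frequency while all contacts are simultaneously
unbound — the complex ends when every contact has let go.  It serves as
the numerical oracle for the product formula.  Two scales matter:

* The *escape frequency* used in simulations defaults to desk scale
  (1e4 s^-1) with correspondingly reduced barriers.  The relation being
  probed is scale-invariant, and simulating a physical 6e12 s^-1
  attempt rate is pointless: event counts, not absolute times, set the
  statistical error.
* The product formula presumes contact dynamics much faster than
  dissociation.  The simulator refuses to run below a separation of
  `min_separation` (default 1000) between the slowest local rate and
  the predicted composite rate.  The exact mean-first-passage solution
  of the same generator is valid at *any* separation, so tests that
  compare the simulator against that dense linear-algebra oracle pass a
  smaller `min_separation` explicitly to probe the crossover.

Even in the separated regime the product formula is approximate: the
equilibrium all-unbound probability is `prod(K_i/(1 + K_i))`, so for
`K_i = 0.05` and two contacts the exact mean lifetime exceeds the
product-formula prediction by ~10%.  The acceptance property asserts
20% agreement, which holds comfortably for small `K_i`.

Local rate *magnitudes* are free parameters of the simulator, not
claims: the analysis lacks an explicit per-contact frequency factor, so
only equilibrium constants (and their voltage factors) are anchored.
Heterogeneous-energy networks are supported; the identical-contact case
is the documented simplification.

## What the synthetic generators emulate — and what they do not

The generators produce every input the fitters consume, with the
statistical structure the analysis assumes:

* `gen_block_timecourse()` — integrates `dB/dt = k_on [Tx] (1 - B) -
  k_off B` across a perfusion schedule, samples `1 - B` every 3 s (the
  pulse rate of the emulated protocol), adds additive Gaussian noise
  (default sigma 0.01 on the normalized current).  With
  `perfusion_tau = 0` each phase is exactly mono-exponential; a
  first-order solution-exchange lag is available (integrated with
  `deSolve`), though no measured exchange time constrains it.  Schedules
  may switch rate constants between segments, emulating
  alternating-solution protocols in which the recovery rate is set
  solely by the currently perfused condition.
* `gen_trace_family()` — control traces rise as
  `(1 - exp(-t/tau_act))^power` (power 4 by default, Hodgkin-Huxley
  like; power 1 available — the ratio analysis is tested to be
  insensitive to this choice, as it must be, since activation kinetics
  are not part of the ratio model).  Toxin traces are the control times
  the two-state block relaxation, starting from the resting unblocked
  fraction given by the four-state model at the holding voltage.
* `gen_titration_table()` — Langmuir values on a 0-100 mM grid with
  log-spaced interior points, multiplicative log-normal noise (default
  sigma 0.10) keeping values positive.  Na+ substitution for constant
  ionic strength is metadata, not modeled.
* `gen_tonic_table()` — model evaluations on the resting and open
  voltage grids with additive Gaussian noise (default 0.03), truncated
  to [0, 1].

Every stochastic output requires an explicit seed and is bit
reproducible.  What the generators deliberately do *not* contain: leak
and capacitive transients, series-resistance and space-clamp artifacts,
electrode drift, slow-inactivation kinetics, stochastic single-channel
gating, or any competition mechanism behind the Langmuir forms.  Passing
recovery tests therefore demonstrate that the estimators invert the
assumed data-generating model at realistic noise, not that real oocyte
recordings are free of systematic error.

## Problem sizes and test design

The test suite exercises: noiseless round trips (generator composed
with fitter is the identity, to near machine precision); algebraic
round trips of the two rate-inversion systems to at least 10 digits;
parameter recovery at realistic noise as medians over 20 seeds (trace
families at 2% trace noise across -40..+60 mV; titrations at 10%
log-normal noise, 3 replicates per concentration; tonic curves at 3%
noise); and the simulator against its dense mean-first-passage oracle
(3 SEM) and the product formula (20%) at 1000 events with two contacts.
These sizes keep the full suite under half a minute while leaving the
statistical assertions comfortably powered.

## Known limitations

* The Boltzmann `Po` is the apparent open probability of a two-state
  gate; multi-state (fourth-power) activation is available only in
  trace synthesis, not in fitting.
* `K_DC`/`Z` trade off in single noisy tonic curves (see above).
* The Langmuir forms are phenomenological; no mechanistic Na+
  competition or ionic-strength correction is attempted.
* The contact-network simulator caps `n` at 16 (dense `2^n` state
  space), and exits only from the all-unbound configuration;
  partial-exit variants are out of scope.
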