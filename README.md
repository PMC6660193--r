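# poreblock

Kinetic, equilibrium and transition-state analysis of peptide-toxin
pore block in voltage-gated K⁺ channels.

Charybdotoxin (CTX) and related scorpion α-KTX peptides block Kv
channels with 1:1 stoichiometry: one bound toxin plugs the outer pore
and stops K⁺ conduction, so the macroscopic current amplitude reports
the blocked fraction directly. `poreblock` is for electrophysiologists
and biophysicists who want to turn such recordings — wash-in/wash-out
time courses, paired control/toxin voltage-step traces, K⁺-titration
tables, tonic-inhibition curves — into rate constants and mechanistic
parameters, without hand-rolled spreadsheets. Because raw oocyte
recordings are bulky, the package also ships seeded synthetic-data
generators that emulate each recording type, so the complete analysis
chain is testable from code alone.

## What it computes

* **Relaxation kinetics.** Mono-exponential fits of block onset and
  recovery invert through `τ_off = 1/k_off`, `τ_on = 1/(k_on[Tx] + k_off)`
  to the association and dissociation rate constants
  (`fit_monoexponential()`, `rates_from_on_off()`). For open channels,
  point-by-point toxin/control trace ratios relax with
  `τ = 1/(k_on[Tx] + k_off)` toward the equilibrium inhibition
  `k_off/(k_on[Tx] + k_off)`; the two-equation system is solved
  per voltage (`trace_ratio()`, `rates_from_relaxation()`,
  `average_then_solve()`), and `k(V) = k(0)·e^{zδFV/RT}` summarizes the
  voltage dependence (`fit_voltage_dependence()`).
* **Ion titration.** Langmuir isotherms
  `k([K⁺]) = k_K + (k_0 − k_K)·K_half/(K_half + [K⁺])` for k_off, k_on
  and K_D versus external K⁺ (`fit_langmuir()`), fold changes between
  the K⁺ limits, per-cation selectivity ratios, and the
  `K_K2/K_K1` lower bound on the external availability of the S1
  filter site in the blocked channel (`s1_availability()`).
* **Four-state model.** Closed/open channels with and without bound
  toxin: Boltzmann gating `Po(V)`, voltage-dependent open-state affinity
  `K_DO(V) = K_DO(0)·e^{zFV/RT}`, steady-state unblocked fraction
  `U/Umax = 1/(1 + [Tx]/K_DO·Po + [Tx]/K_DC·(1−Po))`
  (`unblocked_fraction()`, `fit_tonic_inhibition()`, `fit_gv()`), and
  microscopic reversibility `K_V2 = K_V1·K_DC/K_DO`
  (`kv2_from_cycle()`, `gating_shift()`).
* **Unbinding energetics.** Eyring inversion
  `ΔG‡ = RT·ln(A₀/k_off)` with `A₀ = 6×10¹² s⁻¹`, equal partitioning
  over n contacts (`barrier_from_rate()`, `per_contact_energy()`), the
  compound constant `k_off = A₀·∏K_i·e^{ΣzⱼFV/RT}` (`composite_koff()`),
  and a Gillespie simulation of the 2ⁿ contact-configuration network
  with exit from the all-unbound state
  (`simulate_contact_network()`) — the "wobbling" model of multi-contact
  unbinding.

## Worked example

Simulate a wash-in/wash-out experiment at 0.25 nM toxin with the
high-Na⁺ rate constants (k_on = 73 μM⁻¹s⁻¹, k_off = 0.0062 s⁻¹),
refit it, and recover the rates:

```r
library(poreblock)

sched <- data.frame(start = 30, end = 330, tx_conc = 2.5e-4)  # uM
tc <- gen_block_timecourse(73, 0.0062, sched, t_end = 1200,
                           noise_sd = 0.01, seed = 1)
on_fit  <- fit_monoexponential(tc, window = c(30, 330))
off_fit <- fit_monoexponential(tc, window = c(330, 1200))
rates_from_on_off(on_fit$tau, off_fit$tau, toxin_conc = 2.5e-4)
#> k_on  = 73.66 uM^-1 s^-1
#> k_off = 0.006203 s^-1
#> K_D   = 0.08421 nM
```

The on and off phases fit with τ = 40.6 s and 161.2 s, and the inversion
returns the generating rates within the 1% noise: K_D ≈ 0.084 nM — a
sub-nanomolar blocker whose unbinding takes minutes.

Open-channel kinetics from a trace-ratio family (10-K⁺ low-ionic-strength
parameters, 5 nM toxin, 2% trace noise):

```r
ref <- ctx_reference_params()   # published parameter sets
lr  <- ref$low_ionic$k10
pairs <- gen_trace_family(seq(-40, 60, 20), activation_tau = 2,
  kon0 = lr$kon0, zd_on = lr$zd_on, koff0 = lr$koff0, zd_off = lr$zd_off,
  toxin_conc = 0.005, kdc = 1.84, z_gate = 3.9, v_half = -66,
  t_end = 100, noise_sd = 0.02, seed = 1)
pts <- do.call(rbind, lapply(pairs, function(p) {
  rr <- trace_ratio(p, guard_fraction = 0.1)
  ff <- fit_monoexponential(rr$time, rr$ratio, weights = rr$control^2)
  data.frame(voltage = p$step_voltage, tau = ff$tau / 1000,
             asymptote = ff$baseline)
}))
solved <- average_then_solve(pts, toxin_conc = 0.005)
fit_voltage_dependence(solved$voltage, solved$k_off)
#> k(V=0) = 6.184 (SE 0.79), z_delta = 0.483 e0 (SE 0.092), n = 6
```

One seed at 2% noise recovers the generating k_off(V=0) = 5.6 s⁻¹ and
zδ = 0.4 within its standard errors; the dissociation rate grows e-fold
per ~50 mV, the signature of a pore-plugging blocker sensing K⁺ ions in
the transmembrane field.

State-model and energetic one-liners:

```r
unblocked_fraction(-500, ref$scheme$k10)      # resting I_Tx/I_Con
#> [1] 0.2690058                               #   ~0.3 at 5 nM, K_DC = 1.84 nM
barrier_from_rate(3.3)                        # Eyring barrier, kJ/mol
#> [1] 69.97813
per_contact_energy(barrier_from_rate(3.3), 10)
#> $energy_kT  2.823768      # ~2.8 kT per contact
#> $p_unbound  0.05938176    # each contact unbound ~6% of the time
```

## Documentation

The methods vignette (`vignettes/toxin-block-kinetics.Rmd`) documents
the models, the unit conventions, every tunable parameter with its
default and rationale, the numerical choices inside the fitters, what
the synthetic generators do and do not emulate, and known limitations.
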