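---
title: "A single-compartment model of plateau-potential termination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A single-compartment model of plateau-potential termination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`plateaukit` simulates a spherical single compartment (diameter 10 µm,
surface area πd² ≈ 3.14 × 10⁻⁶ cm², C_m = 1 µF/cm²) whose membrane
potential obeys

C_m dV/dt = −(I_pas + I_VGCC + I_KCa + I_GABA − I_inj),

with four mechanisms:

* **Leak**: I_pas = g_pas (V − E_pas), g_pas = 5 × 10⁻⁵ S/cm²
  (membrane time constant 20 ms), E_pas = −65 mV.
* **Voltage-gated Ca²⁺ channel (VGCC)**: I_VGCC = ḡ_cal · m · h²(ca_i) ·
  GHK(V, ca_i, ca_o). The activation gate m has the high-voltage-activated
  rates α(V) = 0.055(−27.01 − V)/(exp((−27.01 − V)/3.8) − 1) and
  β(V) = 0.94 exp((−63.01 − V)/17); the removable singularity of α at
  −27.01 mV is evaluated by series. Inactivation is purely
  Ca²⁺-dependent, h = k_i/(k_i + ca_i), and enters squared. The driving
  flux is the constant-field (GHK) expression, zero at the Ca²⁺ Nernst
  potential and computed with a series for small arguments so it is
  continuous through V = 0.
* **SK-type Ca²⁺-activated K⁺ current**: I_KCa = ḡ_kca · m³ (V − E_K)
  with a purely Ca²⁺-gated activation m_inf = (ca_i/cac)²/(1 + (ca_i/cac)²)
  and τ_m = [β(1 + (ca_i/cac)²)]⁻¹ / tadj, tadj = 3^((T−22)/10). The
  exponent mismatch between the squared activation curve and the cubed
  conductance is implemented exactly as written in the mechanism lineage.
* **Inhibitory synapse**: a conductance that jumps by g_max at event onset
  and decays single-exponentially (τ_syn) toward E_GABA = −75 mV;
  point-process conductance (µS) is converted to density via the area.

The submembrane Ca²⁺ shell (depth 0.1 µm) integrates the VGCC influx,

dca_i/dt = −10⁴ I_VGCC / (2F·depth) + (ca_inf − ca_i)/τ_r,

with the influx term floored at zero when the VGCC current is outward
(preventing unphysical depletion; the floor can be disabled with
`ca_drive_clamp = FALSE`). Simulations run at 32 °C with dt = 0.025 ms.

## Why plateaus terminate

During a plateau the VGCC current is pitted against SK + leak so the net
current nearly cancels; V sits on a *stable* zero of the instantaneous
(frozen-ca_i) current–voltage relation. As ca_i accumulates, h² erodes the
VGCC and the stable branch drifts down while a *repelling* zero — the
termination threshold — drifts up; when the two meet (a fold), the plateau
collapses spontaneously. An IPSG terminates the plateau early exactly when
it pushes V past the repelling branch; otherwise V recrosses I = 0 and the
plateau resumes its course. Because the VGCC activation gate lags m_inf,
fast IPSPs transiently boost the inward Ca²⁺ current (larger driving
force at still-high m), so the effective threshold is *dynamic*: it
collapses toward hyperpolarized values when approached quickly. This is
why slow inhibition terminates plateaus at smaller amplitudes.

## Parameter choices

Printed constants (geometry, temperature, dt, gating rates, shell depth)
are taken as given. The remaining constants are package choices:

| parameter | default | rationale |
|---|---|---|
| E_pas | −65 mV | typical CA1 rest |
| g_pas | 5 × 10⁻⁵ S/cm² | 20 ms membrane τ |
| E_K / E_GABA | −90 / −75 mV | standard reversals |
| ca_o | 2 mM | recording ACSF |
| ca_inf | 10⁻⁴ mM | resting Ca²⁺ |
| τ_r | 200 ms | slow shell clearance; sets the plateau timescale |
| k_i | 0.01 mM | see below |
| cac | 0.1 mM | see below |
| β_kca, q10 | 0.03 ms⁻¹, 3 (ref 22 °C) | SK kinetics at 32 °C |
| ḡ_cal, ḡ_kca | 1.1288 × 10⁻³, 10⁻⁵ | grid-search calibration |
| τ_syn (analyses) | 5 ms | fast GABA-A at 32 °C |

**k_i and cac.** The Ca²⁺-inactivation constant k_i sets the ca_i scale
the plateau operates at: along the stable branch the net current obeys
|I_sum|/|I_VGCC| ≈ (C_m/1000)·|dV/dca_i| and the branch slope scales as
1/(k_i + ca_i). With the literature mechanism value k_i = 10⁻³ mM the
plateau traverses its bistable window too steeply: no conductance pair
yields a 100–200 ms plateau whose mid-plateau currents nearly cancel, and
with SK half-activation at cac = 0.025 mM the SK current is already
half-active at resting ca_i, so deleting it (the apamin analog)
destabilizes the rest state instead of prolonging the plateau. We
therefore calibrated k_i = 0.01 mM and cac = 0.1 mM, which put
half-inactivation and SK half-activation inside the plateau's ca_i range
(≈0.05–0.2 mM). Both remain configurable.

**ḡ_cal and ḡ_kca** are the outputs of `grid_search()`: a 20 × 20
log-spaced grid over [10⁻⁵, 10⁻²] (S/cm²-scale native units), each cell
probed with a just-suprathreshold 50 ms step (amplitude found by doubling)
and scored by plateau duration. Feasible cells repolarize inside the
100–200 ms band bracketing the experimental mean (140.2 ± 10.2 ms,
n = 51); the default pair is the feasible cell closest to 150 ms
(duration 151.4 ms). `analysis/01_calibrate.R` reproduces this from
scratch.

**τ_syn.** The synaptic decay constant of the termination analyses
defaults to 5 ms, a fast somatic GABA-A decay at 32 °C; the τ sweep
explores 5–80 ms, spanning the slower dendrite-targeting interneuron
kinetics (IPSC decay ≈ 28–47 ms in the recordings this model emulates).

## Numerical scheme

The integrator is a fixed-step (dt = 0.025 ms) operator-split scheme
written in C++: the synaptic conductance is evaluated in closed form
(exact exponential decay, so simultaneous events superpose exactly);
gates advance by exact exponential relaxation toward their steady states
with rates frozen at the step start; V and ca_i advance by an exponential
update in which the ohmic currents (leak, SK, synapse) are integrated
exactly and the GHK current is frozen at a midpoint predictor. The
linearized-exponential treatment of the synapse keeps the step stable for
arbitrarily large inhibitory conductances, which the threshold search's
doubling phase can visit. Because the upstream simulator's implicit
method is not reproducible bit-for-bit, correctness is established
against two references: the same scheme at dt/100 (agreement < 0.5 mV —
in practice < 0.01 mV on plateau protocols) and `deSolve::lsoda` run on
the R-level right-hand side. `initialize_rest()` seeds the settling
relaxation at the most hyperpolarized fixed point of the reduced system
(gates at steady state, ca_i self-consistent); starting from a naive
(E_pas, ca_inf) guess can ignite a spurious plateau during settling,
which never ends when SK is absent.

Fixed points are found by a 0.01 mV sign-change scan over [−100, +20] mV
followed by bisection to 10⁻⁶ mV; stability comes from the sign of dI/dV
(dV/dt = −I/C_m makes dI/dV > 0 stable). Branch linkage across time uses
nearest-V continuation with a 5 mV jump cap; folds end branches. The
"plateau range" for branch counting is V > rest + 15 mV, excluding the
resting stable point. `solve_fixed_points()` accepts either the ca_i of a
simulated trace (the default used by `track_branches()`) or any ca_i
value directly, so an independent ca_i sweep is equally possible.

## Operational definitions

The plateau *duration* runs from stimulus offset to the **final**
crossing of the half-repolarization level (midpoint between V at
offset + 5 ms and rest): an IPSP dip that the plateau survives crosses
the half level transiently and must not count as the end. Presence
requires a ≥ 20 mV elevation and that V stay above the half level for
20 ms and, to be regenerative, for 60 ms (three membrane time
constants) — without the latter a large enough current step inflates a
purely passive tail past the 20 ms rule. A 1 ms running-median is
applied to V first, making the crossing estimate robust to
recording-scale noise (±0.5 mV noise moves the duration by < 5 ms). A
trial is *terminated* only if V reaches within 5 mV of rest inside
130 ms of the IPSG onset **and** the post-onset remaining duration is
under 50% of the control's remaining duration at that onset. The
remaining-duration form of the second clause matters: comparing whole
durations would make a terminated trial at a late onset (say 100 ms into
a 150 ms plateau) arithmetically indistinguishable from a spontaneous
end, and late terminations could never be classified. The 130 ms
deadline sits above the slowest threshold-level collapse (~110 ms) and
below the time a surviving plateau takes to reach the rest band after
the probed onsets (≥ 155 ms); a shorter deadline parks the verdict
boundary on the time-to-rest contour a few percent above the true
all-or-none amplitude cliff, so bisection would return "subthreshold"
traces that have in fact collapsed slowly. Threshold searches bisect to
a 0.5% relative bracket; the all-or-none property is quantified as the
duration jump across ±1% of the threshold amplitude.

## The synthetic cohort

`sample_population()` emulates the recorded cell-to-cell variability by
log-normal jitter (σ = 0.12) on the two calibrated conductances — chosen
so the plateau-duration spread is of the order seen across recorded cells
— simulating each draw, and tabulating durations; draws without a stable
rest or plateau are recorded, not dropped. `corrupt_trace()` adds seeded
Gaussian noise plus a slow sinusoidal drift to V. These surrogates
exercise detection and threshold estimation end to end, but they do not
emulate trial-to-trial biological stochasticity of termination (the
experimental likelihood percentages), recording artifacts beyond
Gaussian noise + drift, or dendritic filtering: passing tests show the
pipeline is correct on model-like data, not that the biophysics
generalizes beyond the single compartment.

## Problem sizes

The shipped analyses use a 400-cell calibration grid (~3 min on one
core), 19-point timing sweeps at three amplitudes, a 5 × 11 amplitude ×
τ plane, five threshold bisections (~25 simulations each), a 51-cell
cohort, and dt/100 reference reruns of three protocols. Each simulation
covers 1.5 s of model time plus 2 s of settling.

## Known limitations

* The model omits Na⁺, HCN, A-type K⁺ and Ca²⁺-activated Cl⁻ currents;
  plateau generation and termination are carried entirely by
  VGCC/SK/leak, so spike-related phenomena are out of scope.
* At the duration-calibrated operating point the mid-plateau net current
  peaks near 11–12% of the dominant current; the product of this
  imbalance ratio with plateau duration is nearly invariant (≈19 ms)
  across the feasible region, so quasi-balance below 10% is only reached
  by parameter sets with durations ≳190 ms. The calibration keeps the
  duration criterion (closest to 150 ms) rather than optimizing the
  balance figure.
* A subthreshold IPSG advances the spontaneous end by a few percent of
  the duration (the hyperpolarization transiently increases Ca²⁺ influx
  through the lagging m-gate); the effect shrinks with faster synaptic
  decay and is ≈9% at the default τ_syn = 5 ms.
* The single exponential with τ = 30 ms used for mock IPSPs is one
  reading of "decayed over 30 ms"; the decay constant is an argument.
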