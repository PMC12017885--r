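---
title: "ingnet: models, calibrations and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ingnet: models, calibrations and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models it
integrates, how each stated calibration constant was obtained, which
parameters were genuinely free and how they were fixed, and what a green
test does and does not establish.

## 1. The question and the model world

Mutually inhibitory fast-spiking interneuron networks can synchronize
into gamma rhythms (the ING mechanism) if each cell receives enough
recurrent synapses.  `ingnet` builds the dentate-gyrus version of this
question: 120 parvalbumin-positive (PV+) interneurons on a 4 mm ring
(the PV+ complement of a ~300 µm slice), connected by distance-dependent
chemical synapses and gap junctions at the measured biological density
(mean in-degree 6.8, SD 2.31), desynchronized by heterogeneous constant
somatic currents N(300 pA, 50 pA), and simulated for 2 s at Δt = 0.1 ms.
The package then measures whether recurrent inhibition synchronizes the
spiking output, sweeping the connection density up to full connectivity
(119 inputs per cell), and embeds the same ring in a scaled dentate
gyrus microcircuit.

## 2. Connectivity: what the data constrain and what they do not

The source connectivity data enter only through two numbers: the mean
(6.8) and SD (2.31) of the chemical in-degree on the standard ring.  The
sigmoid `p(d) = p_max / (1 + exp((d − d_half)/slope))` has three
parameters, so one is free.  Because every ring neuron sees the same
distance profile, the in-degree is Poisson-binomial with closed-form
mean `Σ p(d)` and variance `Σ p(d)(1 − p(d))`; `calibrate_chem_sigmoid()`
fixes `slope = 80 µm` and solves the two moments for the other two
parameters, giving `p_max = 0.2644`, `d_half = 444.9 µm` (an ~0.26
connection probability among near neighbours decaying to zero by
~700 µm).  We verified that the choice of `slope` (40–160 µm, recalibrated
each time) does not measurably change any network-level result.  The
gap-junction sigmoid is unconstrained by printed numbers; the default
(`p_max = 0.6`, `d_half = 150 µm`, `slope = 50 µm`) makes electrical
coupling local and of the same order (~5 junctions/cell) as the chemical
in-degree.

Density sweeps rescale only the sigmoid's amplitude; where the scaled
probability exceeds 1 it clips, which widens the connected neighbourhood
— the same limiting construction that makes the "nearly full" network
literally full (in-degree 119) rather than a refit of an unspecified
near-full sigmoid.

## 3. The fast-spiking cell, and the one genuinely load-bearing choice

The channel-level parameters of the source model live in unavailable
supplementary material, so the cell is a behaviourally calibrated
stand-in: a two-compartment conductance model whose soma carries
fast-kinetics (φ = 5) Na+/K+ spike currents of the classic fast-spiking
class, a passive proximal dendrite (the gap-junction site, nominally
32 µm from the soma; axial coupling tuned for modest somatic-to-dendritic
attenuation), no I_h by default (no sag, no subthreshold resonance —
both verified by tests), and continuous non-silencing firing under step
currents.

One addition was forced by the physics rather than chosen freely: a
strong, fast after-hyperpolarization conductance (increment 8 nS per
spike, τ = 20 ms, K+ reversal).  Without it the f–I slope of this cell
class is ~0.2 Hz/pA, so the stated drive heterogeneity (σ = 50 pA)
produces ~10 Hz of firing-rate dispersion — and we verified by direct
sweeps that *no* connection density up to full connectivity then shows
any synchrony increase, which would contradict the partially synchronous
dense regime the analysis is built around.  The AHP (a hallmark of the
fast-spiking phenotype) saturates the f–I curve (~0.08 Hz/pA at 300 pA)
while leaving firing continuous and non-adapting to silence.  Membrane
area and AHP were then jointly set so an isolated cell fires ~55 Hz at
300 pA and the biologically connected network averages ~53 Hz, and
frozen.  The remaining dynamics (transition location, factorial effect
sizes) are emergent, not tuned.

The dentate-gyrus cells (granule, mossy, HIPP) are single-compartment
variants with spike-triggered adaptation (GC, MC) and I_h (MC, HIPP);
their parameters are assumed, chosen once for plausible population rates
(sparse granule-cell firing ~2–3 Hz against ~40 Hz PV+ firing) and kept
fixed.  Channel-level replication is out of scope.

## 4. Synapses and gap junctions

Chemical synapses are Tsodyks–Markram conductances with instantaneous
rise and single-exponential decay.  The PV→PV synapse: 7.6 nS base
conductance, τ = 1.8 ms, E_rev = −70 mV, depressing (U = 0.3,
τ_rec = 100 ms; both assumed — the source values are unavailable), and a
0.8 ms transmission delay (assumed; some delay is numerically necessary
for event exchange).  The single calibrated constant is the conductance
scale factor (1.5168): under an ideal 0 mV somatic voltage clamp, one
presynaptic spike must evoke a 229 pA peak IPSC.  Because the peak is
linear in the conductance under clamp, `calibrate_ipsc_scale()` is a
one-shot ratio with verification.

Gap junctions are ohmic, dendro-dendritic, all with the same
conductance.  The calibration target is a steady-state soma-to-soma
coupling coefficient of 0.01 (the parameter-setting statement; the same
source elsewhere says "about 0.1" — we follow the parameter statement
and expose the other value via `calibrate_gj(target_cc = 0.1)`; in this
model the tenfold difference does not change the synchrony conclusions).
`calibrate_gj()` exploits the monotonicity of the coupling coefficient
in the junctional conductance (bracketed root search; frozen default
0.0629 nS ≈ 15.9 GΩ junctional resistance).

## 5. Numerics

The integrator is compiled (Rcpp), fixed-step exponential Euler per
compartment and per gating variable, with cross-compartment and
cross-cell (gap-junction) terms explicit at the previous step's
voltages.  The stated Δt is 0.1 ms; internally the engine takes two
substeps per Δt because the fast Na inactivation time constant
(~0.2 ms at φ = 5) is marginally resolved at 0.1 ms, which biases firing
rates by ~1% — enough to break the dt-halving stability property
(spike counts must change by ≤1 per 2 s when Δt is halved; they now do).
Gating rates are evaluated at the midpoint voltage of each substep.
Spikes are detected at upward crossings of 0 mV with a 1 ms lockout;
synaptic events are delivered after the per-edge delay, rounded to the
substep grid (minimum one substep).  All cells start at rest (leak
reversal, gating at steady state); the heterogeneous drive provides
desynchronization — the low-variance-input control shows the expected
initial synchrony decaying within a few hundred ms, as an emergent
behaviour rather than an initialization trick.  Exponential Euler is
unconditionally stable, so divergence is detected by a non-finite or
>1000 mV membrane potential and reported with the neuron and time.

All randomness is generated on the R side (connectivity, drives, input
trains, initial conditions); the C++ core is deterministic, so identical
(configuration, seed) pairs are bit-reproducible.

## 6. Synchrony statistics: conventions that needed deciding

* **Binary bins.** Bins are spike *occupancy* (0/1), not counts;
  otherwise identical trains would not give exactly `k = 1` at large τ.
  `B = floor(T/τ)` bins; an incomplete final bin is discarded.
* **Normalization.** `k_ij = Σ b_i b_j / sqrt(Σ b_i Σ b_j)` — the
  geometric-mean normalization that makes `k` a zero-lag correlation in
  [0, 1]; the non-square-root rendering found in the source text is not
  bounded comparably and fails its own perfect-synchrony example.
* **Inactive neurons.** A neuron with no spikes in [0, T] is excluded
  from the pair average (pairs with an inactive member are dropped and
  the denominator uses retained pairs); undefined measures return `NA`,
  never 0 (0 is a meaningful measurement).
* **Supralinear k quadrature.** The area between `k(τ)` and the chord
  through the origin and `(1/f̄µ, k(1/f̄µ))` is integrated by trapezoid
  over 30 evenly spaced τ in `(0, 1/f̄µ]`, *prepending* τ = 0 with the
  value at the smallest τ.  Without the prepended point the perfect-sync
  closed form `1/(2 f̄µ)` (8.47 ms at 59.03 Hz — the printed reference
  value) is underestimated by ~6.5%; with it the identity is exact, and
  the 30- vs 300-point estimates agree within 5% on smooth curves.
* **Convolved correlation.** Trains are binned onto the simulation grid
  and filtered with a causal exponential (τ = 1.8 ms, the synaptic decay);
  the measure is the mean Pearson correlation over pairs where both
  neurons fire.
* **Band power.** Raw periodogram of the mean-subtracted trace; theta is
  the summed power over 4–12 Hz, gamma over 30–100 Hz.

## 7. Experiments

`density_sweep()` uses 16 target in-degrees {5, 10, 20, …, 110, 119} × 3
seeds by default.  The transition into the partially synchronous state
is localized as the in-degree of the maximal second divided difference
of the 3-point-smoothed, level-averaged `k(0.1/f̄µ)` — a numeric
replacement for "the slope changes here".  With the default cell this
estimator localizes the slope change near ~50 synapses per neuron, below
the ~60–70 reported for the original biophysical model; the direction of
the discrepancy is consistent with the simplified cell's smaller rate
dispersion (stronger AHP rate-compression) lowering the number of
synapses needed for entrainment, and the location is the one emergent
quantity we deliberately did not tune (the constants were frozen on the
anchors in §3–4 before the sweep was evaluated).  The sweep-level
curve itself reproduces the qualitative picture: flat at the
asynchronous ramp value (~0.1) through biological densities, a rise
beginning at several tens of synapses, and a quasi-linear increase to
full connectivity at ~2.5× the ramp value.

`factorial_gj_sy()` runs the 2×2 gap-junction/synapse design (10 seeds
per cell, disjoint seed streams) and tests each response with a balanced
two-way ANOVA (`aov`; verified against hand-computed sums of squares).
`drive_sweep()` raises I_µ at fixed biological connectivity.
`control_variants()` covers the doubled-conductance, equal-in-degree,
identical-network, reversal-potential, input-variance, I_h and 2-D plane
controls; the identical-network control (equal in-degree 8, identical
300 pA, identical initial state) is perfectly synchronous by
construction and anchors the `corr = 1`, `k = 1`, `1/(2 f̄µ)` identities.

## 8. The dentate gyrus stage and its scaling

`build_dg()` places all populations on the shared 4 mm ring coordinate,
keeps the PV ring's distance-dependent connectome, and wires the other
13 projections by the nearest-pool rule (each presynaptic cell connects
to `divergence` cells drawn uniformly from its `n_target` nearest
postsynaptic cells).  Pool sizes, divergences and synaptic constants are
assumed defaults in the style of the classic dentate models and are
labelled as such.  Scaling (default 0.05 → 500 GCs) shrinks populations
proportionally and pools with them; the per-target in-degree is
preserved where the scaled pool allows, and any residual loss is
compensated by scaling the conductance (standard practice for reduced
network models).  One consequence of proportional scaling is that the
6-cell PV ring at desk scale realizes few or no distance-dependent
PV→PV edges, so the desk-scale factorial is a weak (but per-design,
property-level) version of the full-scale null result: granule-cell
synchrony shows no significant dependence on the PV ring's connectivity.
Full scale remains available by configuration but is not exercised in
the tests.

## 9. What the synthetic raster generator does and does not emulate

`make_jittered_raster()` produces rasters with a controllable synchrony
structure (shared reference events copied with probability
`sync_fraction` and Gaussian jitter, independent Poisson remainder,
expected per-neuron rate conserved).  It emulates only the statistical
features the synchrony measures respond to — coincidence mass and its
temporal precision — not refractoriness, rate oscillations, or any
network dynamics.  A green metrics test on these fixtures therefore
validates the *statistics*, not the simulator; simulator-level behaviour
is tested separately against its own invariants (decoupling oracle,
determinism, dt robustness, perfect-synchrony control).  Jitter is
truncated at the window edges (events jittered outside [0, T] are
dropped), a documented bias that is negligible at T = 2 s.

## 10. Known limitations

* The cell is a behavioural stand-in; quantities that depend on channel
  detail (exact transition in-degree, F statistics) are reproduced in
  direction and order of magnitude, not digit-for-digit.
* Tsodyks–Markram parameters beyond the 1.8 ms decay, the transmission
  delay, the gap-junction sigmoid, the sag target and the entire DG
  wiring table are assumed; all are exposed as arguments.
* The supralinear-k measure is unreliable at very low rates (its chord
  normalization inflates; large negative values are possible), matching
  its behaviour in the source analysis.
* No variable-step or implicit solver; single-process execution only.
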