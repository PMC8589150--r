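---
title: "Burst generation and control in a reduced layer-5 pyramidal cell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Burst generation and control in a reduced layer-5 pyramidal cell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Thick-tufted layer-5 pyramidal cells fire occasional high-frequency bursts
of somatic sodium spikes on top of their tonic output. Bursts arise from the
interplay of three regenerative events: somatic/axonal Na⁺ spikes, NMDA
spikes in thin tuft branches, and the dendritic Ca²⁺ spike that initiates in
a hotspot of voltage-gated calcium channels around the main apical
bifurcation (the *nexus*). A backpropagating action potential (bAP) lowers
the hotspot's threshold, so coincident bottom-up (basal) and top-down (tuft)
input is a particularly effective burst trigger (BAC firing). `burstlab`
implements, at desk scale, a complete pipeline for studying the synaptic
conditions of burst generation: a reduced conductance-based model cell, the
stochastic spatiotemporal input scheme, burst statistics, inhibition scans,
and a calcium-dependent plasticity rule.

## The reduced model cell

The morphology (`build_reduced_l5pc()`) is a schematic branched tree that
preserves the landmark path distances the protocols refer to rather than any
reconstructed geometry: oblique branches at ~100 µm, the nexus at 600 µm,
a calcium hotspot over the path-distance span 600–750 µm (the nexus plus the
four primary tuft branches), tuft terminals reaching 1200 µm, and an
iso-distance strip at 1150 µm that touches only distal terminals. A single
short axon-equivalent process (30 × 1.5 µm) carries the spike-initiation
sodium conductance; no further axonal detail is modelled. Because the
reduced tuft has ~5× fewer terminal branches than a reconstruction, each
terminal stands for several real branches and is correspondingly thicker
(2.2 µm); this is the main knob that sets how many clustered synapses a
terminal needs before its NMDA response becomes regenerative.

Compartmentalization (`discretize()`, default ≤ 20 µm per compartment,
345 compartments) and the channel complement (`default_channels()`) follow
standard reduced-model practice:

* transient Na⁺ (m³h) dominating the soma, decaying exponentially along the
  trunk to support the bAP; a separate low-threshold, steeply inactivating
  Na⁺ channel in the axon-equivalent sets the spike threshold (~-58 mV)
  without somatic persistent-sodium instability;
* a fast delayed-rectifier K⁺ at the soma, whose density carries the 1.5×
  scale factor that keeps the spike after-depolarization realistic (exposed
  as `simulation_config(fastk_scale =)`, default on);
* a slow K⁺ (muscarinic-type kinetics) that brakes sustained depolarization,
  plus a slower somatic adaptation K⁺ conductance that limits repetitive
  firing under weak drive;
* high- and low-voltage-activated Ca²⁺ channels concentrated in the hotspot
  (low density in the terminals), and a calcium-activated K⁺ (Hill
  coefficient 4) that terminates spikes and bursts;
* an optional h-current (density 0 by default; none of the protocols here
  need the resting-gradient phenomenology it produces).

Intracellular calcium is a single sub-membrane pool per compartment,
`d[Ca]/dt = -γ·I_Ca/(2F·depth·area) - ([Ca]-Ca0)/τ`, with depth 0.1 µm,
τ = 80 ms, Ca0 = 0.05 µM. γ is the unbuffered fraction of the calcium
current; it is larger at the soma (×12) and in the terminals (×4) than in
the hotspot, standing for region-dependent endogenous buffering, and was
calibrated once together with the channel densities.

The integrator is backward Euler on the branched cable (Hines-ordered
elimination, one pass per direction) at dt = 25 µs over 600 ms runs, with
gates advanced by exact exponential relaxation from voltage-indexed lookup
tables. The passive solver reproduces closed-form cable attenuation to
better than 1 % (see the test suite), and the burst output is unchanged
when dt is doubled. Kinetics are pre-scaled to 34 °C; the temperature is
recorded but there is no live Q10 machinery. E_Ca is fixed at +120 mV (no
GHK correction). Simulations are bit-reproducible given (model, pattern,
configuration).

## Calibration

`check_calibration()` runs the behavioural gates the shipped densities were
tuned against: a single brief somatic pulse elicits exactly one narrow
(<2 ms) action potential; the bAP depolarizes the nexus by ≥ 5 mV without
igniting the hotspot on its own; nexus current injection elicits a 20–50 ms
calcium plateau; pairing a somatic spike with tuft input that is
subthreshold alone ignites a calcium spike and at least two extra somatic
spikes (BAC firing); knocking out the calcium channels collapses the burst
to one spike; and resting calcium stays at baseline, below the plasticity
depression threshold. `calibrate_model(search = TRUE)` re-runs the small
coordinate search over key densities; the shipped defaults pass all gates
without searching.

The calibration intentionally reproduces the study conditions as thresholds
and rates rather than as voltage waveforms: ~33 synchronized tuft synapses
(or ~65 dispersed at σ = 10 ms) on a 750 µm stretch ignite the hotspot,
tuft-class bursts are ~2 spikes at 200–250 Hz, and the basal-tuft delay
window at the 2-spikes/burst level is ~36 ms wide at σ = 3 ms, shrinking to
~12 ms at σ = 9 ms with its center moving toward tuft-leading delays.

## The synthetic input generator

`sample_excitatory()` draws synapse locations uniformly per unit cable
length (basal group over the whole basal tree; tuft group over a random
continuous 750 µm stretch, a single nexus-to-tip branch, or the whole tuft)
and activation times from normal distributions with a shared σ
(per-group σ values are accepted, but all study protocols share one). The sign
conventions follow the worked protocol descriptions: Δt = mean basal onset −
mean tuft onset, so Δt > 0 means the tuft leads; Δt_inh < 0 means inhibition
precedes excitation. One master seed is split deterministically into spatial
and temporal substreams, so a protocol can vary activation times while
holding synapse positions fixed. `sample_inhibitory()` places 20 GABA_A
synapses (1 nS) within ±100 µm of a numbered locus or within a 200 µm
iso-distance strip; `sample_background()` adds spatiotemporally uniform
noise events.

The generator emulates the statistical structure of the study's inputs —
counts, spatial uniformity per unit length, temporal normality, group
offsets — but not presynaptic spike trains, release stochasticity,
short-term plasticity, or correlated background; passing tests therefore
validate the mapping from input statistics to burst statistics, not the
full richness of in-vivo input.

## Burst statistics

Somatic spikes are upward 0 mV crossings of the soma trace (`detect_spikes`;
in this reduced model the count is insensitive to moving the threshold
within −20..0 mV — late intra-burst spikes peak only a few mV above zero, a
narrower insensitive band than a detailed model's). Spikes group into bursts
by inter-spike interval ≤ 20 ms (`group_bursts`); spikes/burst of a trial is
the size of the largest group (isolated spikes are not averaged in; the
per-group mean is available as an option). The intra-burst rate of a group
is (n−1)/duration, isolated spikes counting as 0 Hz bursts, and the
aggregate over trials is the spike-count-weighted mean (unweighted as an
option). Delay-window curves are summarized by the width and center of the
contiguous super-level set at 2 spikes/burst containing the curve maximum,
with linear interpolation at the crossings. Burst classes follow the count
rule: tuft-NMDA for > 40 tuft and < 120 basal synapses, coincidence for
> 150 basal and < 100 tuft. CV and Fano factor of ISIs use population
moments. Scan dispersion is reported as the SD of 10 batch means of 20
trials.

## Plasticity

The calcium-dependent rule drives each synaptic weight toward
Ω([Ca²⁺]) = 0.25 + σ(80(Ca−θ_p)) − 0.25·σ(80(Ca−θ_d)) at rate η([Ca²⁺])
(`omega`, `eta`, `update_weight`), with θ_p = 0.4 µM, θ_d = 0.25 µM. η is a
saturating Hill function (K = 0.3 µM, n = 4, η_max = 1 s⁻¹) — the rule's
published form fixes only its qualitative shape, so these are calibrated
package defaults. Because Ω saturates at 1.0, the absolute efficacy starts
at w_init = 0.5 (the midpoint of the Ω range) and reported weights are
normalized to that initial value; "protected" is a normalized weight within
1 ± 0.02. The calcium signal at a synapse is its compartment's pool (no
separate spine pool). Ten non-overlapping input repetitions are the default
protocol; 10 vs 20 repetitions change final weights by < 5 %. Without
closely timed inhibition, a calcium spike potentiates the whole excited
branch in this model.

## Numerical and design choices

* Voltage grid for gate tables: −120..60 mV at 0.25 mV, rebuilt per dt.
* The hotspot span (600–750 µm) is a documented assumption — its spatial
  extent is not constrained by published measurements; the chosen span makes
  "inhibition 200–400 µm distal to the nexus" adjacent-but-outside.
* `select_span` grows a connected stretch from a uniformly drawn start
  segment, choosing uniformly among branch continuations; it bridges
  silently through off-target nodes (e.g. the soma between sibling basal
  branches) so a fraction of a disconnected region remains meaningful.
* Excitatory release is deterministic; AMPA and NMDA components have equal
  0.4 nS peak conductances (the AMPA-only control sets NMDA to zero);
  the magnesium block is 1/(1 + [Mg]/3.57·e^(−0.062V)).
* Thresholds are located by bisection at 5-synapse resolution with 20 seeded
  instantiations per count, burst in ≥ 50 % of repetitions as the criterion
  (the ≥ 95 % variant is a parameter).
* Scan problem sizes default to 20 repetitions per grid cell in tests and
  scripts and 100 in the shipped presets; all scans are reproducible
  bit-for-bit from their master seed.

## Known limitations

The reduced cell reproduces the study's threshold-and-rate phenomenology,
not its detailed-model waveforms, and three behaviours fall short of the
source phenomenology even after calibration. (1) Dendritic inhibition at
the printed strength (20 × 1 nS) barely perturbs burst generation here: the
reduced hotspot spreads the igniting conductance over ~3000 µm² of membrane,
so the same absolute inhibitory conductance that silences a compact nexus is
diluted (a ~3× larger inhibitory dose does suppress bursts). Consequently
inhibition-timing windows and inhibition-conditioned plasticity maps are
much weaker than in the detailed model. (2) Very strong basal-only input
(≥ 200 synapses) mostly produces single spikes rather than 3–4-spike
coincidence bursts; the strong-basal rate region is carried by cells with
some tuft co-activation. (3) With NMDA removed, strong tuft input still
ignites the hotspot in about a third of instantiations, versus essentially
never at these counts in the detailed model. These are properties of the
reduced morphology and are documented rather than patched by moving
parameters away from the printed values.
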