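---
title: "A thalamocortical network model of sleep stages under neuromodulatory control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A thalamocortical network model of sleep stages under neuromodulatory control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnet)
```

## The scientific question

Vigilance states — wake, the spindle-rich N2 stage, slow-wave N3 sleep and
REM — correspond to characteristic rhythms of thalamocortical electrical
activity, and they track the levels of a small set of neuromodulators:
acetylcholine (ACh) and histamine (HA) fall during non-REM sleep and rise in
REM, while extracellular GABA rises in non-REM and falls in REM. `somnet`
implements a biophysical network model in which these three exogenous
variables control a minimal set of intrinsic and synaptic parameters, and
asks whether that minimal set suffices to produce the electrographic
signatures of each stage and the transitions between them.

## Model structure

The network is one-dimensional and topographic: 500 cortical pyramidal cells
(PY), 100 cortical interneurons (IN), 100 thalamocortical relay cells (TC)
and 100 thalamic reticular cells (RE). Connectivity is local; each
projection has a radius in source-layer cell indices after proportional
center mapping between layers (PY–PY 5, TC–RE 8, RE–TC 8, TC–PY 10, TC–IN 2,
PY–TC 10, PY–RE 8). For every target the printed maximal conductance of a
projection is treated as the total synaptic input, divided by the realized
fan-in; this keeps input magnitudes comparable for edge cells (a
per-synapse reading is selectable via `network_spec(normalization =
"per_synapse")`).

Cortical cells are two-compartment models: a dendritic compartment with
capacitance 0.075 uF/cm^2 carrying K+-leak, Cl−-leak, fast Na+, persistent
Na+, high-threshold Ca2+, Ca2+-dependent K+ and M-type K+ currents, and a
zero-capacitance axo-somatic compartment carrying the spike-generating fast
Na+ and delayed-rectifier currents. The somatic voltage solves the algebraic
current balance `g_cs (Vd − Vs) = I_Na,s + I_K,s + I_Nap,s` at every step by
fixed-point iteration to 1e-6 mV; the map is strongly contractive because
only the instantaneous persistent-Na activation depends on the somatic
voltage itself. TC and RE cells are single compartments with fast spike
currents, a low-threshold Ca2+ current, and — in TC cells — the
hyperpolarization-activated cation current Ih with calcium-regulated
kinetics: open channels can be locked open by a Ca2+-bound regulatory
factor (`C <-> O`, `P0 + 4Ca <-> P1`, `O + P1 <-> OL`), so that Ca2+ entry
during repeated rebound bursts progressively locks Ih open, depolarizes the
cell, and terminates a spindle sequence.

Synapses are transmitter-gated kinetic models: first-order AMPA, NMDA (with
a sigmoidal magnesium-block factor) and GABA-A schemes driven by a 0.5 mM,
0.3 ms transmitter pulse per presynaptic spike, and a second-order
G-protein cascade with a quartic nonlinearity for GABA-B. Intracortical
excitatory connections depress (7% per spike, 700 ms recovery). Spontaneous
miniature PSPs on PY–PY, PY–IN and IN–PY connections are the model's only
noise source: each connection carries an inhomogeneous Poisson process whose
hazard, `(2/(1+exp(-(t-t0)/20))-1)/250` per ms, restarts at zero after each
presynaptic spike and saturates at 4 Hz.

## Neuromodulator mapping

Each stage maps to multiplicative parameter scalars: AChPY, AChTC, AChRE
scale the K+-leak conductances of the cortical, relay and reticular cells
(ACh *reduces* K+-leak in PY/IN/TC and *increases* it in RE, so the scalars
move oppositely); LACh scales AMPA conductances of the PY–PY, TC–PY and
TC–IN projections; LGABA scales GABA-A conductances of IN–PY, RE–RE and
RE–TC (the two halves are independently addressable for the minimal-model
experiments); ShiftHA shifts the Ih activation curve,
`h_inf = 1/(1+exp((V+75+ShiftHA)/5.5))`. The printed per-stage values are:

| stage | ACh% | HA% | GABA% | AChPY | AChTC | AChRE | LACh | LGABA | ShiftHA |
|-------|-----|-----|-------|-------|-------|-------|------|-------|---------|
| awake | 100 | 100 | 100 | 1.00 | 1.00 | 1.00 | 1.00 | 1.00 | −8 |
| N2    |  80 |  40 | 115 | 1.25 | 1.25 | 0.80 | 1.25 | 1.15 | −3 |
| N3    |  50 |  30 | 130 | 1.80 | 2.00 | 0.50 | 2.00 | 1.30 | −2 |
| REM   | 115 |  10 |  75 | 0.85 | 0.85 | 1.15 | 0.80 | 0.75 |  0 |

The AChTC value for N3 is not part of the printed sequence (which lists
only three values for four stages); we ship 2.0, the value the
thalamus-only N3 minimal-model preset uses. Note the sign convention of
ShiftHA: a *more negative* parameter moves the half-activation voltage
*rightward* (−8 puts it at −67 mV), so the awake state — highest HA — has
the most Ih, consistent with histamine depolarizing relay cells through
this current. `continuous_scalars()` interpolates the four anchors
piecewise-linearly in each level (LGABA is exactly GABA/100) with linear
end-segment extrapolation, which reproduces the anchors exactly and is
monotone throughout.

Propofol anesthesia is modeled as a lengthening of the GABA-A IPSP decay
plus reduced ACh and HA. "Increased by 150%" is read as multiplying the
decay time constant by 2.5; the ×1.5 reading is selectable and both are
exercised by the tests. The tonic-GABA variants scale the miniature-IPSP
conductance per stage (A: fixed; B: microdialysis profile 115/130/75%;
C: co-release profile 85/70/125%) while the phasic GABA-A conductance stays
at its awake value.

## Numerical scheme

The engine advances all gating variables by exponential Euler with
voltage-dependent rates tabulated on a 0.05 mV grid, and voltages by
explicit Euler at dt = 0.02 ms; synapse open fractions use the exact
piecewise-exponential solution, shared per presynaptic neuron and receptor
type. Per-target synaptic conductances are accumulated with prefix sums
over the contiguous fan-in ranges of the 1-D topology, so the cost per step
is linear in cells rather than edges. Miniature releases are event-driven:
per-connection next-release times are drawn by Newton inversion of the
closed-form integrated hazard and held in a binary heap with lazy
invalidation when the presynaptic cell spikes. A single 64-bit RNG stream
seeded from the run seed makes runs bit-reproducible; recorded voltages are
downsampled to 1 kHz.

Convergence behaves as expected for an explicit method: subthreshold
trajectories agree with a 10x-finer reference to well under 1 mV RMS, and
stimulus-locked burst onsets to under 1 ms, while tonic spike trains show
slow phase drift (spike counts change by under 5% when dt is halved).

## Calibration of unprinted parameters

The printed parameter set fixes conductance maxima but not rate functions,
reversal potentials, compartment areas, or calcium-pool dynamics. We adopt
the canonical formulations of the prior model lineage (Mainen–Sejnowski
reduced cortical kinetics; Traub fast currents with a −50 mV threshold
shift, Huguenard/McCormick low-threshold Ca2+ and Destexhe Ih for the
thalamus) and document the following choices, all in
`inst/extdata/constants.yaml`:

* Reversals: E_Na +50, E_K −95, cortical Cl-leak −68, TC leak −75, RE leak
  −77, E_h −40 mV; thalamic Ca2+ reversal from the Nernst equation at the
  instantaneous internal concentration, cortical HVA Ca2+ fixed at +140 mV.
  The TC leak reversal is the one deliberate calibration: at −75 mV the
  awake relay cell rests near −59 mV and stays silent, while the reduced Ih
  and raised K+-leak of N2/N3 hyperpolarize it into the range where
  low-threshold bursts ignite spontaneously — the seed of spontaneous
  spindling.
* Calcium pools: influx 10/(2F·d) per unit Ca2+ current with shell depth
  1 um in the thalamus (5.18e-5 mM/ms per uA/cm^2, 5 ms relaxation to
  0.24 uM) and a thin 0.1 um shell in cortex (5.18e-4, 165 ms, 0.1 uM
  floor). The thalamic depth matters: a much larger influx factor keeps
  resting Ca2+ high enough to lock Ih open permanently, which pins TC cells
  in a depolarized state and abolishes all stage differences.
* Compartment areas: 1e-6 cm^2 soma with dendritic/somatic area ratios 165
  (PY) and 50 (IN); TC 2.9e-4, RE 1.43e-4 cm^2; axo-somatic coupling
  10 MOhm. These reconcile mS/cm^2 channel densities with uS synaptic
  conductances.
* The persistent-Na activation is capped at 0.02 (`0.02/(1+exp(-(V+42)/5))`),
  which makes the printed dendritic density of 2.0 mS/cm^2 an effective
  0.04 mS/cm^2; without the cap the current either pins cells at
  depolarized plateaus or blocks spiking entirely.
* The miniature-PSP quantum is the printed conductance divided by the
  *canonical* (full-network) fan-in, independent of the simulated scale; a
  quantum that grew with coarser networks pushed the desk-scale thalamus
  into continuous spindling.

## What the model reproduces

With these choices the full-scale model produces: a sparse awake state
(mean PY rate ~1 Hz, IN ~2 Hz, TC silent, RE nearly silent) that responds
to a 100 ms / 1.5 nA DC probe of the thalamus with a transient and returns
to baseline; an N2 state with spontaneous waxing-and-waning 10–11 Hz
spindle episodes recurring every 4–8 s and lasting 2–4 s on the
spectrogram readout, generated by the TC delta/RE burst loop and terminated
by calcium-locking of Ih; and stage-dependent thalamic hyperpolarization
tracking the printed K+-leak and Ih changes.

## Known limitations

The principal limitation of this implementation is the N3 cortical slow
oscillation. Under the printed conductance set the cortical network shows
local slow population events but does not develop globally synchronized
Up/Down alternation; the N3 LFP therefore remains dominated by
thalamically-generated spindle-band activity rather than a sub-1 Hz peak.
Extensive exploration of the unprinted parameters (leak reversals, calcium
pools, synaptic normalization, recurrent strengths) either left the cortex
asynchronous or destroyed the correct awake and N2 regimes. Checks that
depend on the cortical slow oscillation — the N3 spectral peak, the
cortex-only minimal models that should switch between activated, slow
oscillating and quiescent states, the spindle–delta correlation sign flip,
and the slow-oscillation half of the propofol contrast — are implemented
and run faithfully, and fail honestly where the slow oscillation is
missing. The desk-scale (reduced network) surrogates inherit this and are
additionally more excitable in the thalamus, so several minimal-model
verdicts that hold at full scale are unstable at desk scale.

Other simplifications: levels of the three neuromodulators are exogenous
drives (no closed-loop dynamics); there are no gap junctions, facilitation
or receptor desensitization; the network is one-dimensional with flat
boundaries; REM is characterized only coarsely (desynchronized activity
with occasional brief alpha-band events).

## What the synthetic data can and cannot show

All acceptance inputs are generated by the simulator itself; the
signal-analysis chain (band power, PLV, event detection, mixture
clustering) is exercised on model LFPs — arithmetic means of PY dendritic
voltages — plus constructed fixtures with known ground truth. Passing
tests therefore demonstrate internal consistency of the model and analysis
code, not agreement with any particular recording: real field potentials
have volume conduction, 1/f backgrounds, artifacts and non-stationarities
that the model LFP lacks. The analysis functions accept plain columnar
input so they can be applied to external recordings, with band presets for
model, animal and human conventions.

## Problem sizes used by the test-suite

The tests scale simulations to keep the default run tractable: awake
verification uses the full network for 20 s; N2 spindle statistics the full
network for 40 s (60 s in `scripts/acceptance.R`); N3 the full network for
20 s; the minimal-model, propofol, correlation and GABA-modulation checks
use the reduced 100/20/20/20 desk-scale network with 8–20 s segments; the
clustering surrogate uses an 8-point neuromodulator grid with 12 s trials
and three seeds. Single-cell convergence checks run 2 s at dt = 0.02
against dt = 0.002.

## A small worked example

A desk-scale four-stage run and its feature table:

```{r example, eval = FALSE}
net <- assemble_network(reduced_network_spec())
cfg <- sim_config(stage_schedule("awake", "n2", durations_s = 10), seed = 1,
                  discard_s = 2)
sim <- simulate_network(net, cfg)
firing_rates(sim, by_stage = TRUE)
lfp <- compute_lfp(sim, "all")
spindle_stats(lfp, method = "spectrogram")
autoplot(sim)
```

The full-scale equivalents of every figure-level experiment are available
as presets (`experiment_presets()`, `run_preset()`), and the
neuromodulator-space map via `run_sweep()` + `cluster_states()` +
`project_clusters()`.
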