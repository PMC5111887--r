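# somnet

A conductance-based thalamocortical network model of sleep stages under
neuromodulatory control, with the signal-analysis chain needed to
characterize its rhythms.

## What it is for

During the night the brain cycles through wake, spindle-rich N2 sleep,
slow-wave N3 sleep and REM. These electrographic states track the levels of
acetylcholine (ACh), histamine (HA) and GABA. `somnet` is for computational
neuroscientists who want to simulate and analyze how a *minimal* set of
neuromodulator actions — scaling of K⁺-leak, AMPA and GABA-A conductances
and a shift of the h-current activation curve — moves a biophysical
thalamocortical network between these states.

The network contains 500 two-compartment pyramidal cells (PY) and 100
interneurons (IN) in cortex, and 100 single-compartment relay (TC) and 100
reticular (RE) cells in thalamus, wired with local one-dimensional
topography. Cortical cells obey

    C_m dV_d/dt = − AChPY·I_K-leak − I_Cl-leak − I_Na − I_Nap − I_Ca − I_KCa − I_Km − I_syn
    g_cs (V_d − V_s) = − I_Na,s − I_K,s − I_Nap,s     (zero-capacitance soma)

and thalamic cells carry fast spike currents, a low-threshold Ca²⁺ current
and (TC) the calcium-gated h-current

    I_h = g_h ([O] + k[O_L]) (V − E_h),   h∞(V) = 1 / (1 + e^{(V+75+ShiftHA)/5.5})

whose open state O can be locked open (O_L) by Ca²⁺-bound regulation —
the mechanism that makes spindles wax and wane. Synaptic currents follow
first-order transmitter-gated kinetics, e.g.

    I_AMPA = LACh · g_syn [O] (V − E_AMPA),   I_GABA-A = LGABA · g_syn [O] (V − E_GABA)

with miniature PSPs (an inhomogeneous Poisson process with hazard
`(2/(1+e^{−(t−t₀)/20})−1)/250` per ms) as the only noise source. Per-stage
scalars (AChPY, AChTC, AChRE, LACh, LGABA, ShiftHA) are tabulated for
awake/N2/N3/REM and interpolated for arbitrary (ACh, HA, GABA) levels.

The analysis side computes simulated LFPs (group means of PY dendritic
voltage), band powers (delta 0.5–4 Hz, spindle 7–15 Hz), pairwise
phase-locking values, spindle and slow-oscillation event detection, a
spindle–delta correlation test, and Gaussian-mixture clustering of network
regimes with AIC model selection, projected back into neuromodulator space
as ellipsoids.

## Worked example: spontaneous N2 spindles

```r
library(somnet)

net <- assemble_network(network_spec())        # full 500/100/100/100 network
cfg <- sim_config(stage_schedule("n2", durations_s = 60), seed = 1, discard_s = 5)
sim <- simulate_network(net, cfg)              # ~4 min on one core

firing_rates(sim)
#>   pop   rate_hz
#> 1 PY       1.65
#> 2 IN       8.79
#> 3 TC       8.15
#> 4 RE      11.6

lfp <- compute_lfp(sim, "all")                 # mean of all 500 PY dendrites
spindle_stats(lfp, method = "spectrogram")[c("n", "median_duration_s")]
#> $n                      8
#> $median_duration_s      3.5
```

Eight spindle episodes appear spontaneously in 55 s of analyzed N2, at
10–11 Hz, lasting a median of 3.5 s and recurring every several seconds —
thalamically generated, waxing and waning through calcium-locking of the
h-current, with no external stimulation. `autoplot(sim)` draws the raster and LFP;
`plot_spectrogram(lfp)` the sliding-window spectrogram.

Figure-level experiments are packaged as presets:

```r
run_preset("fig5_d", seed = 1, scale = "reduced")  # thalamic ACh+HA reduction
ft <- run_sweep(sweep_grid(), scale = "full")      # neuromodulator grid sweep
m  <- cluster_states(ft)                           # GMM + AIC regime count
project_clusters(m, ft[, c("ach", "ha", "gaba")])  # ellipsoids in modulator space
```

A thin command-line wrapper is installed at `inst/exec/somnet`
(`somnet simulate|analyze|experiment|sweep`).

## Known limitation

The cortical slow oscillation of N3 does not globally synchronize in this
implementation, so the N3 LFP remains dominated by spindle-band activity;
see the methods vignette (`vignettes/sleep-stage-model.Rmd`) for the
calibration choices, the evidence, and which checks this affects.
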