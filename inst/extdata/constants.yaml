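# somnet model constants, version 1.
# Every numeric parameter of the cell, synapse and network models lives here.
# Values are loaded once per session and may be overridden from a run config
# (see somnet_constants()). Units: mV, ms, mS/cm^2, uS, mM, uF/cm^2, cm^2.
#
# Kinetic rate *forms* are fixed in code; the numbers below parameterize them.
# Cortical voltage-gated channels follow the reduced two-compartment cortical
# model lineage (Mainen-Sejnowski style kinetics); thalamic channels follow
# the Traub fast spike currents and Huguenard/McCormick low-threshold Ca and
# h-current formulations, as used by prior thalamocortical sleep models.
version: 1
temperature_C: 36.0

areas:
  soma_cm2: 1.0e-6          # axo-somatic compartment area (cortical cells)
  rho_py: 165.0             # dendritic/somatic area ratio, PY
  rho_in: 50.0              # dendritic/somatic area ratio, IN
  tc_cm2: 2.9e-4            # single-compartment TC area
  re_cm2: 1.43e-4           # single-compartment RE area

reversals:
  e_na: 50.0
  e_k: -95.0
  e_cl_cortex: -68.0        # Cl- (fixed) leak in cortical dendrite
  e_leak_tc: -75.0
  e_leak_re: -77.0
  e_h: -40.0
  e_ca_cortex: 140.0        # fixed HVA Ca reversal (cortex)
  e_ampa: 0.0
  e_gaba: -90.0
  ca_o_mM: 2.0              # extracellular Ca for thalamic Nernst reversal

cortex:
  cm: 0.075                 # uF/cm^2 (dendrite; soma treated as zero-capacitance)
  kappa_Mohm: 10.0          # axial coupling resistance soma<->dendrite
  py:
    g_kleak: 0.007
    g_clleak: 0.023
    g_na_dend: 0.8
    g_nap_dend: 2.0
    g_ca_dend: 0.012
    g_kca_dend: 0.015
    g_km_dend: 0.012
    g_na_soma: 3000.0
    g_k_soma: 200.0
    g_nap_soma: 15.0
  in:
    g_kleak: 0.034
    g_clleak: 0.006
    g_na_dend: 0.8
    g_nap_dend: 0.0
    g_ca_dend: 0.012
    g_kca_dend: 0.015
    g_km_dend: 0.012
    g_na_soma: 2500.0
    g_k_soma: 200.0
    g_nap_soma: 0.0
  kinetics:
    q10_na: 2.3             # Q10s, base temperature 23 C (cortical channels)
    q10_k: 2.3
    q10_km: 2.3
    q10_kca: 2.3
    base_temp_cortex: 23.0
    na_shift: 0.0           # voltage offset applied to fast-Na rate functions
    nap_act_max: 0.02       # persistent Na: m_inf = nap_act_max/(1+exp(-(V+42)/5))
    nap_tau: 0.2
    kca_alpha_per_mM: 10.0  # alpha = kca_alpha_per_mM * [Ca]
    kca_beta: 0.02
    km_rate: 1.0e-4
  calcium:
    drive: 5.18e-4          # mM per ms per (uA/cm^2); thin shell (0.1 um)
    floor_mM: 1.0e-4
    tau_ms: 165.0

thalamus:
  cm: 1.0
  tc:
    g_leak: 0.01
    g_kleak: 0.007
    g_na: 90.0
    g_k: 10.0
    g_lca: 2.5
    g_h: 0.015
  re:
    g_leak: 0.05
    g_kleak: 0.016
    g_na: 100.0
    g_k: 10.0
    g_lca: 2.2
  kinetics:
    vtr: -50.0              # Traub fast-current threshold shift (Na and K)
    vtr_k: -50.0
    it_tc_mshift: 57.0      # m_inf = 1/(1+exp(-(V+shift)/6.2))
    it_tc_hshift: 81.0
    q10_it_m: 3.55
    q10_it_h: 3.0
    base_temp_it: 24.0
    it_re_mshift: 52.0
    it_re_hshift: 80.0
  calcium:
    drive: 5.18e-5          # shell depth 1 um
    floor_mM: 2.4e-4
    tau_ms: 5.0

ih:                         # calcium-gated h-current (TC cells only)
  k1: 2.5e+7                # mM^-4 ms^-1 : P0 + 4Ca -> P1
  k2: 4.0e-4                # ms^-1      : P1 -> P0 + 4Ca
  k3: 1.0e-1                # ms^-1      : O + P1 -> OL
  k4: 1.0e-3                # ms^-1      : OL -> O + P1
  k_locked: 2.0             # conductance weight of the locked-open state
  vhalf: 75.0               # h_inf = 1/(1+exp((V + vhalf + shift)/slope))
  slope: 5.5
  tau_floor: 20.0           # tau_s = tau_floor + 1000/(exp((V+71.5)/14.2)+exp(-(V+89)/11.6))

synapse:
  t_pulse_mM: 0.5           # transmitter concentration during a release pulse
  t_pulse_ms: 0.3
  ampa: {alpha: 1.1, beta: 0.19}
  nmda: {alpha: 0.072, beta: 0.0066, mg_vhalf: -25.0, mg_slope: 12.5}
  gabaa: {alpha: 5.0, beta: 0.18}
  gabab: {k1: 0.52, k2: 0.0013, k3: 0.098, k4: 0.033, kd: 100.0, hill: 4}
  depression: {use: 0.07, tau_rec: 700.0}   # intracortical excitatory only
  mini:
    rate_tau: 20.0          # hazard = (2/(1+exp(-dt/rate_tau))-1)/rate_cap
    rate_cap: 250.0
    g_py_py: 0.033          # uS, AMPA minis on PY from PY
    g_py_in: 0.02           # uS, AMPA minis on IN from PY
    g_in_py: 0.02           # uS, GABA-A minis on PY from IN

network:
  n_py: 500
  n_in: 100
  n_tc: 100
  n_re: 100
  radii:
    py_py: 5
    py_in: 1
    in_py: 5
    py_tc: 10
    py_re: 8
    tc_py: 10
    tc_in: 2
    tc_re: 8
    re_tc: 8
    re_re: 8
  gsyn_uS:                  # printed totals; divided by realized fan-in
    py_py_ampa: 0.024
    py_py_nmda: 0.001
    py_in_ampa: 0.012
    py_in_nmda: 0.001
    in_py_gabaa: 0.024
    py_tc_ampa: 0.005
    py_re_ampa: 0.015
    tc_py_ampa: 0.02
    tc_in_ampa: 0.02
    tc_re_ampa: 0.05
    re_tc_gabaa: 0.05
    re_tc_gabab: 0.02
    re_re_gabaa: 0.05

engine:
  dt_ms: 0.02
  lfp_rate_hz: 1000.0
  spike_threshold_mV: 0.0
  spike_refractory_ms: 2.0
  soma_tol_mV: 1.0e-6
  soma_max_iter: 60
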