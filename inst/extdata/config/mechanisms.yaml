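# Mechanism, ion, and protocol defaults for the reduced CA1 model.
# Units: mV, ms, mM, um; conductance density S/cm2; current density mA/cm2;
# synaptic conductance uS; temperature Kelvin.
#
# Exchanger constants follow the Weber-type electrochemical/allosteric
# formulation; K[Ca] follows the Destexhe-type Hill form with an SK-like
# calcium affinity; channel densities are the frozen calibration of the
# reduced complement (chosen once so the model rests near -70 mV, fires to
# gamma drive in the physiological band, and backpropagates a single
# somatic spike).

passive:
  cm: 1.0            # uF/cm2
  ra: 150.0          # ohm cm
  g_pas: 2.5e-5      # S/cm2
  e_pas: -65.0       # mV

ions:
  ca_i: 5.0e-5       # mM (50 nM)
  na_i: 10.0         # mM
  ca_o: 2.0          # mM
  na_o: 140.0        # mM
  temperature_K: 307.15

reversal:
  ena: 50.0
  ek: -77.0
  eca: 120.0         # fixed L-type reversal; the exchanger uses concentrations

na:                  # transient Na, m3h
  gbar_soma: 0.12
  gbar_dend: 0.04
  gbar_axon: 0.30

kdr:                 # delayed rectifier, n4
  gbar_soma: 0.036
  gbar_dend: 0.012
  gbar_axon: 0.06

ka:                  # A-type, a*b, density grows with distance from soma
  gbar: 0.002
  dist_factor_per_100um: 0.3   # gbar * (1 + f * d/100)

cal:                 # L-type Ca, m2
  gbar: 5.0e-6

kca:                 # Ca2+-activated K+, m2, Hill n = 2
  gbar: 1.0e-2
  alpha: 4.8e+05     # ms^-1 mM^-2 (half-activation at ~250 nM)
  beta: 0.03         # ms^-1
  hill_n: 2
  tau_min: 0.1       # ms

ncx:                 # Na/Ca exchanger, allosteric x electrochemical
  vmax: 0.1          # mA/cm2 scale
  gamma: 0.35
  ksat: 0.27
  km_na: 87.5        # mM
  km_ca: 1.38        # mM
  km_ca_act: 1.25e-4 # mM (125 nM)
  n_hill: 2

capool:
  shell_depth_um: 0.1
  tau_decay_ms: 80.0
  ca_rest: 5.0e-5
  ca_min: 1.0e-6

simulation:
  dt: 0.025          # ms
  v_init: -70.0      # mV
  spike_threshold: 10.0   # mV, somatic detection threshold

protocols:
  gamma_drive:
    n_synapses: 10
    rate_hz: 40
    noise: 1.0
    min_distance_um: 100
    region: apical_primary
    duration_ms: 1000
    tau_ms: 2.0      # single-exponential synapse decay
    e_rev: 0.0
    weight_uS: 0.006
  bap:
    amp_nA: 2.0
    dur_ms: 2.0
    delay_ms: 10.0
    tstop_ms: 80.0
  stdp:
    delta_t_ms: 10.0       # EPSP onset to bAP onset
    window_ms: 35.0
    n_pairings: 1
    settle_ms: 50.0
    tail_ms: 150.0
    readout_ms: 60.0
    epsp_tau_rise: 0.5
    epsp_tau_decay: 5.0
    epsp_weight_uS: 0.0008
    epsp_e_rev: 0.0
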