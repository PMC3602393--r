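# Default biophysical and experimental parameters.
#
# Source tags:
#   [published]         value stated in the source study's text or tables
#   [traub-default] value from the Traub-lineage CA3 compartmental models
#   [assumed]       substitute default (the study's supplementary parameter
#                   tables are not publicly archived); chosen from standard
#                   hippocampal modelling practice and tuned once so the
#                   control network entrains at 20/30/40 Hz
# Every value here can be overridden through the `params` argument of the
# builder functions or an experiment config file.

membrane:
  cm_uF_cm2: 3.0          # [traub-default] membrane capacitance
  ra_ohm_cm: 100.0        # [traub-default] axial resistivity
  g_leak_mS_cm2: 0.1      # [traub-default] leak conductance density
  e_leak_mV: -60.0        # [traub-default] leak reversal / resting potential
  e_na_mV: 55.0           # [traub-default]
  e_ca_mV: 80.0           # [traub-default]
  e_k_mV: -75.0           # [traub-default]
  ca_tau_ms: 13.3         # [traub-default] calcium pool decay time constant
  ca_phi_per_area: 8.0  # [assumed] chi units per (uA/cm^2) per ms, scaled by 1/area

# Maximum conductance densities, mS/cm^2, by cell type and compartment role.
# Channel set: Na, Ca, KDR (delayed rectifier), KA, KAHP, KC. [assumed],
# patterned on the Traub CA3 distributions along the somato-dendritic axis.
channel_densities:
  pyramidal:
    soma:            {Na: 60.0, Ca: 2.0, KDR: 25.0, KA: 5.0, KAHP: 0.3, KC: 10.0}
    initial_segment: {Na: 60.0, Ca: 0.0, KDR: 30.0, KA: 0.0, KAHP: 0.0, KC: 0.0}
    axon:            {Na: 60.0, Ca: 0.0, KDR: 30.0, KA: 0.0, KAHP: 0.0, KC: 0.0}
    apical_dendrite: {Na: 2.0,  Ca: 2.0, KDR: 2.0,  KA: 0.0, KAHP: 0.3, KC: 5.0}
    basal_dendrite:  {Na: 2.0,  Ca: 2.0, KDR: 2.0,  KA: 0.0, KAHP: 0.3, KC: 5.0}
  interneuron:
    soma:            {Na: 45.0, Ca: 1.0, KDR: 20.0, KA: 0.2, KAHP: 0.1, KC: 2.0}
    initial_segment: {Na: 60.0, Ca: 0.0, KDR: 30.0, KA: 0.0, KAHP: 0.0, KC: 0.0}
    axon:            {Na: 60.0, Ca: 0.0, KDR: 30.0, KA: 0.0, KAHP: 0.0, KC: 0.0}
    apical_dendrite: {Na: 2.0,  Ca: 1.0, KDR: 2.0,  KA: 0.0, KAHP: 0.1, KC: 2.0}
    basal_dendrite:  {Na: 2.0,  Ca: 1.0, KDR: 2.0,  KA: 0.0, KAHP: 0.1, KC: 2.0}

# Compartment counts. "full" matches the source morphologies (64-compartment
# pyramidal cell, 46-compartment interneuron [published]); "reduced" is the
# desk-scale default used by the test-suite and sweeps.
morphology:
  default: reduced
  pyramidal:   {full: 64, reduced: 8}
  interneuron: {full: 46, reduced: 5}
  dims_um:     # [assumed] cylinder dimensions (length x diameter)
    reduced: {soma: [40.0, 25.0], initial_segment: [30.0, 1.5], dendrite: [150.0, 4.0]}
    full:    {soma: [20.0, 10.0], initial_segment: [30.0, 1.0], dendrite: [60.0, 2.0]}

# Kinetic synapse defaults. tau2 = 3 ms for AMPA is the stated control value
# [published]; the remaining time constants are [assumed] standard hippocampal
# values (the supplementary synapse table is unavailable).
synapses:
  AMPA:   {tau1_ms: 0.5, tau2_ms: 3.0,   e_rev_mV: 0.0,   g_max_nS: 1.0,  delay_ms: 1.0}
  NMDA:   {tau1_ms: 5.0, tau2_ms: 100.0, e_rev_mV: 0.0,   g_max_nS: 0.15, delay_ms: 1.0}
  GABA_A: {tau1_ms: 0.5, tau2_ms: 7.0,   e_rev_mV: -75.0, g_max_nS: 2.0,  delay_ms: 1.0}
  mg_mM: 1.0   # [assumed] extracellular magnesium for the NMDA block

# Population sizes [published].
populations:
  pyramidal: 160
  basket: 30
  chandelier: 30
  calretinin: 20

# Projection probabilities and targets. [assumed] substitutes for the
# unavailable supplementary connectivity table; dense enough for collective
# oscillation at desk scale. Calretinin cells project only onto other
# interneurons; chandelier cells target the pyramidal axon initial segment.
connectivity:
  - {source: pyramidal,  target: pyramidal,  p: 0.10, role: apical_dendrite, kind: excitatory, spine: true}
  - {source: pyramidal,  target: basket,     p: 0.30, role: apical_dendrite, kind: excitatory, spine: false}
  - {source: pyramidal,  target: chandelier, p: 0.30, role: apical_dendrite, kind: excitatory, spine: false}
  - {source: pyramidal,  target: calretinin, p: 0.30, role: apical_dendrite, kind: excitatory, spine: false}
  - {source: basket,     target: pyramidal,  p: 0.30, role: soma,            kind: inhibitory, spine: false}
  - {source: basket,     target: basket,     p: 0.20, role: soma,            kind: inhibitory, spine: false}
  - {source: chandelier, target: pyramidal,  p: 0.30, role: initial_segment, kind: inhibitory, spine: false}
  - {source: calretinin, target: basket,     p: 0.30, role: apical_dendrite, kind: inhibitory, spine: false}
  - {source: calretinin, target: chandelier, p: 0.30, role: apical_dendrite, kind: inhibitory, spine: false}

# Click-train drive. Each click is a synchronous AMPA volley onto the
# mid-apical compartment of a fraction of pyramidal cells. [assumed]
drive:
  fraction: 1.0
  g_max_nS: 50.0
  jitter_ms: 1.0
  duration_ms: 1200.0
  transient_ms: 200.0

integration:
  dt_ms: 0.025            # exponential-Euler step
  v_init_mV: -70.0
  spike_threshold_mV: 0.0
  refractory_ms: 2.0

spectral:
  segment_ms: 500.0       # Welch segment (2 Hz resolution)
  overlap: 0.5
  window: hann
  band_halfwidth_hz: 2.0

# Illness / wellness metric calibration.
metrics:
  target_decrease: 0.26   # [published] clinically calibrated 40 Hz deficit
  illness_tolerance: 0.075 # [published] +/- 7.5 % band tolerance at 20 and 30 Hz
  wellness_tolerance: 0.10 # [published] 10 % band tolerance for drug trials
  falloff: 0.26           # [assumed] linear score falloff scale

# Lesion grids [published]: NMDA g_max reduction 0-45 % step 5; spine density
# reduction 0-60 % step 5; 7 GABA ordered pairs (tone reduction, weight
# increase). The default pair list is the uniform diagonal; the secondary
# point's pair (-37.5, +30) is off this diagonal and can be supplied via
# config (see vignette).
lesion_grid:
  nmda: [0.0, 0.05, 0.10, 0.15, 0.20, 0.25, 0.30, 0.35, 0.40, 0.45]
  spine: [0.0, 0.05, 0.10, 0.15, 0.20, 0.25, 0.30, 0.35, 0.40, 0.45, 0.50, 0.55, 0.60]
  gaba_pairs:
    tone:   [0.0, 0.075, 0.15, 0.225, 0.30, 0.375, 0.45]
    weight: [0.0, 0.10,  0.20, 0.30,  0.40, 0.50,  0.60]

# Virtual-medication grids [published], Table 1 (5 x 5 x 5 x 3 x 4 = 1500).
drug_grid:
  ampa_gmax: [0, 20, 40, 60, 80]
  alpha2:    [0, 15, 30, 45, 60]
  nmda:      [0, 20, 40, 60, 80]
  ampa_tau2: [1, 3, 5]
  cr_weight: [0, 20, 40, 60]
  ltp_weight_per_20pct_nmda: 0.047  # [published] LTP coupling of the NMDA drug

# Negative-control agents.
control_drugs:
  phenytoin:  {doses: [0.0, 0.05, 0.10, 0.15, 0.20, 0.25, 0.30, 0.35, 0.40, 0.45, 0.50]} # Na g_max reduction
  nifedipine: {doses: [0.0, 0.05, 0.10, 0.15, 0.20, 0.25, 0.30, 0.35, 0.40, 0.45, 0.50, 0.55, 0.60, 0.65, 0.70, 0.75, 0.80]} # Ca g_max reduction [published: max 80 %, steps of 5]
  ampakine:   # 6 g_max levels x 5 tau2 levels = 30 iterations [published]
    gmax_increase: [0, 10, 20, 30, 40, 50]
    tau2_increase: [0, 20, 40, 60, 80]
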