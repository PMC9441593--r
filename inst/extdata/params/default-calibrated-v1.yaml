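# Default calibrated parameter set for the mossy-fiber granule cell model.
# Units: lengths um, voltages mV, times ms, Cm uF/cm2, Rm kOhm*cm2, Ri Ohm*cm,
# conductance densities mS/cm2, permeabilities cm/s, synaptic conductances nS,
# concentrations mM, temperature K.
#
# Gate parameterization (HH-type): for each gate,
#   x_inf(V) = 1 / (1 + exp(-(V - vhalf)/k))      (k < 0: inactivation gate)
#   tau_x(V) = tau_base + tau_amp * exp(-((V - tau_vmid)/tau_sigma)^2)
# Markov Ca2+ chain C0<->C1<->C2<->C3<->C4<->O:
#   forward  C_{i-1}->C_i: (5-i) * a * exp(+V/kf),  i = 1..4
#   backward C_i->C_{i-1}:      i * b * exp(-V/kb)
#   C4->O: kon, O->C4: koff (voltage independent)
# Calibration: gate/chain rate parameters were fit (tools/calibrate.R) so the
# single-compartment clamp protocols reproduce the reference kinetics; see
# the methods vignette.
name: default-calibrated-v1

passive:
  cm_uf_cm2: 1.0
  rm_kohm_cm2: 60.0
  ri_ohm_cm: 70.0
  e_leak_mv: -81.0
  v_rest_mv: -80.0

na:
  gbar_axon_ms_cm2: 50.0     # axon, boutons, filopodia, collaterals
  gbar_soma_ms_cm2: 10.0     # soma
  gbar_dend_ms_cm2: 2.0      # dendrites (unmeasured; low to keep dendrites
                             # from spiking under large local EPSPs)
  e_rev_mv: 50.0
  m:
    vhalf: -48.7
    k: 3.5
    tau_base: 0.04
    tau_amp: 0.162478
    tau_vmid: -40.0
    tau_sigma: 30.0
  h:
    vhalf: -64.0
    k: -3.0
    tau_base: 0.50
    tau_amp: 5.639765
    tau_vmid: -65.0
    tau_sigma: 20.0

k:
  gbar_ms_cm2: 36.0
  e_rev_mv: -85.0
  "n":
    vhalf: -50.0
    k: 6.0
    tau_base: 0.25
    tau_amp: 2.0
    tau_vmid: -50.0
    tau_sigma: 40.0
  hk:                         # multiplicative Kv1.4-like inactivation gate
    vhalf: -60.0
    k: -5.0
    tau_base: 24.5
    tau_amp: 15.0
    tau_vmid: -75.0
    tau_sigma: 20.0

ca:
  cao_mm: 2.0
  cai_mm: 1.0e-4
  temp_k: 296.0
  subtypes:
    pq: {pbar_cm_s: 4.0e-5, a: 1.284464, kf: 25.0, b: 0.513785, kb: 25.0, kon: 13.0, koff: 9.101332}
    "n":  {pbar_cm_s: 1.6e-5, a: 1.250527, kf: 25.0, b: 0.500211, kb: 25.0, kon: 12.0, koff: 8.398360}
    r:  {pbar_cm_s: 0.5e-5, a: 0.980898, kf: 25.0, b: 0.381460, kb: 25.0, kon: 4.0, koff: 1.871610}

syn_glu:                      # dendritic glutamatergic input (somatic EPSP)
  tau_rise_ms: 0.2
  tau_decay_ms: 2.5
  e_rev_mv: 0.0
  gmax_total_ns: 18.45178     # calibrated to a 20.0 mV somatic EPSP

gaba:                         # axonal GABA-A point sources (spillover-like)
  tau_rise_ms: 14.0
  tau_decay_ms: 30.0
  e_rev_mv: -65.0             # default; presets -78 (shunt) / -52 (high Cl)
  n_per_cylinder: 10
  gmax_per_source_ns: 0.078   # calibrated so the high-chloride (-52 mV)
                              # condition reduces peak AP-evoked ICa to 51.7%
  cl_out_mm: 154.0
  temp_k: 296.0

geometry:
  soma: {diam: 15.0, length: 15.0}
  dend_trunk: {diam: 0.35, length: 120.0}
  dend_primary: {diam: 0.5, length: 150.0, count: 3}
  dend_secondary: {diam: 0.35, length: 180.0, per_primary: 3}
  axon: {diam: 0.4, length_per_cylinder: 150.0, n_cylinders: 10,
         first_diam_prox: 1.0}
  bouton: {diam: 7.0, length: 7.0, count: 10}
  filopodium: {diam: 0.1, length: 20.0, per_bouton: 4}
  collateral: {diam: 0.2, length: 200.0, origins_um: [50.0, 100.0, 200.0],
               bouton_diam: 7.0, bouton_length: 7.0, filopodia: false}

sim:
  dt_ms: 0.05                 # default integration step
  dt_fine_ms: 0.005           # clamp characterization (resolves sub-ms tau)
  max_seg_um: 10.0
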