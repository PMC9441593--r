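# mfaxon

Compartmental simulation of subthreshold voltage signaling along
hippocampal mossy fiber axons.

Dentate granule-cell axons carry two kinds of analog signal on top of the
action potential: somatodendritic EPSPs that spread passively for hundreds
of micrometers into the axon (*EPreSPs*, excitatory presynaptic
potentials), and depolarizing *GABA-EPreSPs* produced by spillover
activation of axonal GABA<sub>A</sub> receptors.  Both reach the large
en-passant mossy fiber boutons and modulate the presynaptic Ca²⁺ influx of
a passing spike.  `mfaxon` reconstructs this system as a multicompartment
cable model — a granule cell with soma, dendrites, ten 150 µm axonal
cylinders, ten boutons with filopodia, and hilar collaterals — equipped
with Hodgkin–Huxley-type Na⁺ (m³h) and inactivating K⁺ (n⁴·hk) channels and
six-state Markov models of the P/Q-, N- and R-type presynaptic Ca²⁺
channels (C0⇌C1⇌C2⇌C3⇌C4⇌O, voltage-dependent closed transitions, a
voltage-independent opening step, GHK flux).  The branched cable equation

  C_m dV/dt = −Σ_c g_c(V − E_c) − I_Ca(V) + I_axial + I_syn + I_inj

is integrated implicitly (Crank–Nicolson on a Hines-ordered tree solve,
Rush–Larsen gate updates, backward Euler on the Markov master equation) in
a compiled core.

The experiment layer reproduces, end to end:

* single-compartment voltage-clamp characterization of every channel
  (activation/inactivation/deactivation time constants, I–V curves);
* passive EPreSP propagation and its length constant
  (λ_EPreSP ≈ 448–457 µm);
* action-potential propagation and the presynaptic Ca²⁺ current at the
  first bouton;
* modulation of that current by a preceding EPreSP (peak reduced to ≈ 90%)
  or by depolarizing axonal GABA conductances (peak reduced to ≈ 52% at
  E_GABA = −52 mV);
* a paired-pulse clamp test demonstrating the absence of Ca²⁺-channel
  facilitation.

## A worked example

```r
library(mfaxon)
p <- default_params()          # the calibrated parameter set

# EPreSP propagation: peaks at the ten boutons, exponential length constant
ep <- simulate_epresp(p)
ep$fit$tau
#> [1] 457.1828
ep$soma_peak_mv
#> [1] 19.99958

# sodium-channel kinetics under the clamp protocol, at the -40 mV test pulse
subset(characterize_channel("na", p), v_test == -40)
#>   v_test i_peak_pa tau_act_ms tau_inact_ms
#> 4    -40 -6680.504  0.2501523       1.7502

# modulation of the AP-evoked presynaptic Ca2+ current by a preceding EPreSP
r <- simulate_epresp_plus_ap(p)
c(r$peak_ratio_pct, r$charge_ratio_pct)
#> [1] 91.50398 89.71422

# ... and by depolarizing GABA-EPreSPs (E_GABA = -52 mV)
g <- simulate_gaba_epresp_plus_ap(p, e_gaba = -52)
c(g$peak_ratio_pct, g$charge_ratio_pct)
#> [1] 51.71417 46.61533

paired_pulse_ca_test(p, interval_ms = 50)$ratio
#> [1] 0.9999996
```

The EPreSP peak decays to 1/e over ≈ 457 µm of axon (the fitted λ);
the preceding EPreSP lowers the spike-evoked Ca²⁺ peak at bouton 1 to
91.5% of control and its charge to 89.7%; the calibrated GABA conductance
halves the peak (51.7%).  See the methods vignette
(`vignettes/mossy-fiber-model.Rmd`) for the model equations, the
calibration procedure, and a frank account of what the defaults do and do
not reproduce (in particular why the GABA *charge* ratio computes to ≈ 47%
in this parameterization).

A thin command-line front end is included:

```sh
Rscript inst/cli/axonsim.R epresp --out results/
Rscript inst/cli/axonsim.R gaba-ap --e-gaba -52 --out results/
```

## Parameter sets

All model constants live in one YAML file
(`inst/extdata/params/default-calibrated-v1.yaml`), loaded by
`default_params()`; every field carries its unit.  `tools/calibrate.R` is
the script that produced the calibrated rate constants (clamp kinetics) and
synaptic conductances (20 mV somatic EPSP; 51.7% GABA peak ratio).
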