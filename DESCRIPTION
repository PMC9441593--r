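Package: mfaxon
Title: Compartmental Simulation of Subthreshold Voltage Signaling Along
    Hippocampal Mossy Fiber Axons
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multicompartment cable-equation model of a dentate granule cell
    and its mossy fiber axon, with Hodgkin-Huxley type axonal sodium and
    (inactivating) potassium channels, six-state Markov models of P/Q-, N-
    and R-type presynaptic calcium channels with Goldman-Hodgkin-Katz flux,
    and synaptic conductance sources.  Implements voltage-clamp
    characterization of each channel, passive propagation of subthreshold
    excitatory presynaptic potentials (EPreSPs) along the axon and the fit
    of their length constant, action-potential propagation, and the
    modulation of action-potential-evoked presynaptic calcium current by
    preceding EPreSPs and by depolarizing GABA-A mediated axonal
    conductances (GABA-EPreSPs).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
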