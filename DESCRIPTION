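Package: ca1sim
Title: Compartmental Simulation of Na+/Ca2+ Exchange and Ca2+-Activated
    K+ Currents in CA1 Pyramidal Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multicompartment cable-equation simulator for CA1
    pyramidal neurons, built to probe how the electrogenic Na+/Ca2+
    exchanger (NCX) and the Ca2+-activated K+ conductance (K[Ca]) shape
    orthodromic firing, backpropagating action potentials, and
    spike-timing-dependent plasticity (STDP). Provides SWC morphology
    reading and apical-region classification (trunk, oblique, tuft),
    d_lambda spatial discretization, a Crank-Nicolson integrator with an
    exact O(n) Hines tree solver, Weber-type NCX kinetics (allosteric x
    electrochemical factors), Destexhe-type K[Ca] kinetics, a
    submembrane calcium pool, synaptic drive and current-clamp
    protocols, SPIKE-synchronization and waveform metrics, and the four
    configured in-silico experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
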