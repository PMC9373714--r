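Package: dacircuit
Title: Biophysical Simulation of the Dopamine-Modulated VTA-NAc-mPFC Microcircuit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Multi-compartment Hodgkin-Huxley simulation of a small
    mesocorticolimbic circuit (medium spiny neurons of the nucleus
    accumbens, pyramidal neurons and PV/CB interneurons of the medial
    prefrontal cortex) with kinetic AMPA/NMDA/GABA-A receptor synapses,
    Goldman-Hodgkin-Katz calcium fluxes, and dopamine modelled as a
    scalar input that linearly interpolates selected ion-channel
    parameters between their dopamine-depleted (0 percent) and normal
    (100 percent) values.  Includes a fixed-step Runge-Kutta 2(3)
    integrator with a compiled core, spike and burst statistics, local
    field potential construction, Welch power spectra, short-time
    Fourier transforms, and per-frequency group comparison statistics
    (DiffRatio and dBm difference maps) for contrasting low-dopamine
    (depression-like) and normal conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    yaml,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
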