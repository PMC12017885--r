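Package: ingnet
Title: Biophysical Simulation of Recurrent Inhibitory Interneuron Networks
Version: 0.1.0
Authors@R: person("ingnet", "developers", role = c("aut", "cre"),
    email = "ingnet@example.org")
Description: Conductance-based simulation of ring and plane networks of
    fast-spiking parvalbumin-positive interneurons with distance-dependent
    chemical and electrical (gap-junction) coupling, Tsodyks-Markram
    short-term synaptic dynamics, and a scale-configurable dentate gyrus
    microcircuit.  Provides spike-train synchrony statistics (binned
    coherence, frequency-corrected coherence, supralinear coherence area,
    convolved-output correlation), spectral band power, experiment drivers
    (connectivity-density sweeps, two-way factorial designs with ANOVA,
    input-drive sweeps) and synthetic raster generators for testing the
    statistics without running simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
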