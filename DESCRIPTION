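Package: porelab
Title: Pore Geometry, Ion Transport and Blockade-Event Analysis for
    Engineered Protein Nanopores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for nanopore engineering studies that combine
    biased molecular-dynamics trajectories with single-channel recordings.
    Computes slice/ring local pore radius profiles along the channel axis,
    per-residue RMSF after rigid superposition, z-resolved ion densities,
    and total and per-species (K+, Cl-) ionic currents by the
    charge-displacement method.  Detects blockade events in current traces,
    fits falling-exponential dwell-time distributions, estimates capture
    frequencies from inter-event intervals, classifies translocation versus
    bumping from the voltage dependence of dwell times, and assembles the
    comparative statistics (percent change, fold change, per-base
    translocation time, diameter-dwell correlation).  Includes synthetic
    generators (drift-diffusion ions in a channel under a uniform axial
    field, pseudo-atom channels with prescribed radius profiles, two-state
    current traces with Poisson arrivals and exponential dwells) that
    provide ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    bio3d,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
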