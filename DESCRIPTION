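Package: smfretkin
Title: Single-Molecule FRET Trace Simulation, Idealization and Dwell-Time Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of single-molecule FRET (smFRET) intensity
    traces for ligand-binding kinetics of membrane receptors. Generates
    donor/acceptor photon traces from a continuous-time Markov binding scheme
    (Gillespie simulation) with crosstalk, gamma detection asymmetry, emission
    noise and single-step photobleaching; converts traces to FRET with the
    standard crosstalk/gamma corrections; detects bleaching change points and
    applies molecule-selection criteria; compiles per-movie normalized FRET
    histograms with across-movie standard errors; fits single and global
    multi-component Gaussians and Hill dose-response curves; idealizes traces
    by segmental k-means (SKM); builds transition-density plots; extracts
    dead-time-merged dwell sequences; and fits rate constants of linear
    two-site binding schemes by dwell-time maximum likelihood, including the
    independent-sites constraint and the dissociation constant Kd.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
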