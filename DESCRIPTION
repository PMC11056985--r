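Package: helixfriction
Title: Internal Friction Analysis of Helix-Coil Folding Trajectories
Version: 0.1.0
Authors@R:
    person("Helix", "Friction Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates local and global internal friction coefficients of
    alpha-helical peptides from hydrogen-bond time series and end-to-end
    distances. Provides a synthetic trajectory generator (continuous-time
    Markov hydrogen-bond kinetics, helix-geometry end-to-end distances,
    Brownian tracer particles), hydrogen-bond detection and
    RMSD-from-ideal-helix structural observables, two-state folding kinetics
    from autocorrelation analysis, censoring-aware dwell-time extraction with
    log-binned exponential-mixture fits, hydrogen-bond/end-to-end free-energy
    surfaces with per-level histogram centers, Einstein-relation local
    friction and end-to-end-step global friction, mean-square-displacement
    tracer diffusion with relative-viscosity conversion, and linear/power-law
    extrapolation of friction coefficients to zero viscosity.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
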