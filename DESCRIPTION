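Package: mlcmd
Title: Machine-Learned Centroid Molecular Dynamics for Nuclear Quantum
    Effects in Model Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify and learn nuclear quantum effects in
    molecular simulations at classical cost. Provides thermostatted
    path-integral molecular dynamics on ring polymers, including
    fixed-centroid sampling of exact quantum centroid forces; an
    analytic theory of ring-polymer delocalization (Matsubara-mode
    bead widths with free-particle and harmonic-oscillator bounds)
    and the resulting locality bounds on quantum force corrections;
    Feynman-Hibbs effective pair potentials; a numerically exact
    one-dimensional fixed-centroid path-integral oracle; a localized
    atomic-environment regression model (Gaussian-type-orbital
    descriptors with per-element neural networks, trained by extreme
    learning machine initialisation plus Levenberg-Marquardt force
    matching) for the quantum centroid force correction; and
    classical-cost centroid molecular dynamics driven by the learned
    correction, with radial distribution function, diffusion and
    pressure analysis on built-in model systems.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    parallel,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
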