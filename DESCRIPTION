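Package: tubefission
Title: Phase-Field Modelling of Dynamin-Driven Constriction and Fission of
    Lipid Tubules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mesoscopic simulation of membrane tubule constriction and
    fission by dynamin helices.  Implements a diffuse-interface
    (phase-field) Canham-Helfrich elastic free energy with bending,
    Gaussian-curvature and tension contributions on axisymmetric domains,
    a dynamin coat pressure model coupled to the membrane through an
    interaction energy, Allen-Cahn (maximum-dissipation-rate) relaxation
    with semi-implicit Fourier-spectral time stepping, trajectory
    observables (neck radii, critical states, activation energies,
    normalized lumenal conductance, fission times), and the companion
    sharp-interface and linearized-elasticity theory (equilibrium and
    constricted radii, tubule Green's function, neck-splitting threshold,
    analytic fission-time formula).
License: MIT + file LICENSE
Encoding: UTF-8
SystemRequirements: FFTW3 (>= 3.3)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
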