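Package: trilayer
Title: Three-Site Implicit-Solvent Coarse-Grained Lipid Membrane Modelling and Evolutionary Parametrization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An ultra-coarse-grained lipid membrane toolkit in which each lipid
    is three interaction sites (one hydrophilic head, two hydrophobic tails)
    and the solvent is implicit. Provides the model energetics with a
    force-shifted 6/0.5 nonbonded form and GROMACS-compatible tabulated
    potential export, a compact Langevin-dynamics engine with semi-isotropic
    Berendsen pressure coupling, estimators for seven membrane properties
    (area per lipid, area compressibility, line tension, bending modulus from
    the undulation spectrum, phase-transition temperature, lateral radial
    distribution function and transverse density profile), an Earth Mover's
    Distance comparator, and a genetic algorithm that tunes the six
    force-field parameters against target properties. Mixed-resolution
    support covers Lennard-Jones cross-interaction tables and a peptide
    tilt-angle objective.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
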