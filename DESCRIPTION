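Package: plaquefem
Title: Parametric Plane-Stress Finite-Element Analysis of Calcified
    Atherosclerotic Plaque
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parameterized structural analysis of calcified atherosclerotic
    plaque cross-sections. Generates idealized half cross-sections of a
    stenosed artery (non-diseased wall, fibrous plaque and cap, lipid
    crescent, homogenized calcification agglomerate), meshes them with
    region-aware graded quadratic triangles, solves orthotropic linear
    plane-stress equilibrium under luminal pressure, and post-processes
    maximum principal stress and cap deformation. Study drivers sweep cap
    thickness, calcification gap and composite elasticities to locate
    rupture thresholds (300 kPa critical stress; 65 micrometre thin cap),
    including rule-of-mixtures homogenization of the calcification
    agglomerate and a quasi-static pulsatile pressure envelope.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
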