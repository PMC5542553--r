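Package: biofilmDEM
Title: Individual-Based Biofilm Modelling with Discrete-Element Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A mechanistic individual-based model (IbM) of microbial
    communities. Spherical agents grow by Monod kinetics, divide, excrete
    extracellular polymeric substances (EPS), decay and die; solute fields are
    solved to quasi-steady state on a voxel grid by an explicit
    advection-diffusion-reaction scheme; and mechanical relaxation uses
    discrete-element (spring-dashpot) contact, EPS-mediated adhesive springs
    and Stokes drag under an imposed linear shear flow. Includes scenario
    presets for quiescent growth, growth under shear, and erosion/detachment of
    a pre-grown biofilm, together with morphology metrics (height, RMS
    roughness, porosity), composition, active-layer and detached-cluster
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    igraph,
    MASS,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    fitdistrplus
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'agents.R'
    'analysis.R'
    'biofilmDEM-package.R'
    'io-snapshots.R'
    'kinetics.R'
    'lifecycle.R'
    'mechanics.R'
    'network-presets.R'
    'nutrient.R'
    'parameters.R'
    'scenarios.R'
    'units.R'
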