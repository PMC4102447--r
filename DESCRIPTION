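Package: funnelbind
Title: Enhanced-Sampling Free Energy Methods for Ligand Unbinding on Toy Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, testable implementation of the free-energy machinery
    used to dissect drug unbinding from kinases: well-tempered metadynamics
    with a cylindrical funnel restraint, umbrella sampling unbiased by the
    weighted histogram analysis method (WHAM), one-dimensional adaptive
    biasing force (ABF) estimation, and the Woo-Roux restraint-decomposed
    absolute binding free energy assembly (conformational, orientational and
    translational restraint terms, the bulk surface term S*, the separation
    integral I*, the binding constant K_bind and its standard-state free
    energy). The samplers run on analytic toy potentials - including
    two-dimensional "separation distance x loop conformation" binding
    landscapes with induced-fit coupling - so that every estimator can be
    validated against dense quadrature of the same landscape. Includes
    PLUMED-style HILLS/COLVAR/PMF text file input and output, residence-time
    bookkeeping from dissociation barriers, and a reproduction mode for the
    published free energy decomposition table of crizotinib binding to ROS1
    kinase.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
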