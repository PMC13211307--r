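Package: enerfeas
Title: Energetic Feasibility Domains for Ecological Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Geometry of energetic feasibility for ecological networks
    described by energy-based generalized Lotka-Volterra dynamics. Builds
    the nested capture, initialization and maturation domains in the space
    of mass-specific energy capture rates under a total energy supply
    constraint, computes their volumes (exactly for polytopes, by
    Hit-and-Run with multiphase Monte Carlo for quadratically constrained
    convex bodies), and derives feasibility probabilities, feasibility
    partitions over all candidate subcommunities, critical and optimal
    supply levels, average-diversity curves, and ensemble-level trends via
    logit-space functional data analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    quadprog,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
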