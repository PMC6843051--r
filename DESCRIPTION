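Package: mcgpath
Title: Minimalist Coarse-Grained Protein Models for Conformational Transition Paths
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A minimalist C-alpha coarse-grained (MCG) protein model with a
    partial structural bias toward a reference conformation: Morse contact
    potentials split into local and non-local pairs at an 8.5 Angstrom
    reference-distance cutoff, secondary-structure-dependent pseudo bond-angle
    and dihedral terms, and holonomic bond-length restraints. Includes a BAOAB
    Langevin-dynamics engine for sampling transitions between two reference
    states under dual-biased force fields, the sigma transition-progress
    coordinate built on Kabsch superposition RMSDs, sigma-binned potential
    energy profiles, and principal-path (regularized k-means) clustering with
    Bayesian-evidence selection of the regularization weight. Synthetic
    generators for ideal helices, strands, two-state hinge proteins and arc
    point clouds make the whole pipeline testable without external structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    tibble,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
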