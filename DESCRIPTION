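Package: fcaffinity
Title: Structure-Based Prediction of Fc/FcRn Binding Affinity for Antibody Fc Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to model antibody Fc variants on a reference Fc/FcRn
    co-complex structure, extract interface features (accessible and buried
    surface areas, solvation energies, hydrogen bonds, salt bridges and
    related contact counts), curate variant/affinity tables measured at
    different pH values into harmonized learning sets, train and
    cross-validate four regressors (linear, support vector, random forest,
    multi-layer perceptron) on log10 dissociation constants, select features
    by iterative importance elimination and correlation pruning, and generate
    in silico random variant libraries for affinity screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    e1071,
    ranger,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
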