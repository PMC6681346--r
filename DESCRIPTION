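Package: phenotax
Title: Chemotaxonomy of Plant Species from CuO-Oxidation Phenol Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for chemotaxonomic classification of plant species from
    quantified phenolic compound profiles released by mild alkaline CuO
    oxidation. Computes lignin-phenol group sums (p-hydroxy, vanillyl,
    syringyl, coumaryl, benzoic and hydroxy-benzoic acids), source proxy
    ratios (S/V, C/V), and the Shannon-Wiener phenol diversity index;
    applies a transparent threshold rule for identifying Erica species from
    relative coumaryl and benzoic acid abundances; provides Ward/Euclidean
    hierarchical clustering and PCA front-ends, from-scratch CART decision
    trees and a bagged random forest with Gini feature importance, a
    replicated train/test and cross-validation evaluation harness, and a
    Dirichlet-based synthetic profile generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    mclust,
    e1071,
    rpart,
    randomForest
Config/testthat/edition: 3
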