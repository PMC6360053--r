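Package: nbmda
Title: Neighborhood-Based Prediction of miRNA-Disease Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts candidate miRNA-disease associations from a sparse
    bipartite association network. Disease similarity is computed from an
    ontology graph (decayed semantic contributions over ancestor terms) and
    fused with Gaussian interaction-profile kernel similarity; miRNA
    functional similarity is fused the same way. K-nearest-neighbour
    recommendation densifies the association network into two augmented
    variants, and every disease-miRNA pair is scored by a quadrangular
    common-neighbour / local-community-link index geometric-averaged over
    the original and augmented networks. Includes leave-one-out and
    repeated k-fold cross-validation harnesses with rank-based ROC/AUC,
    and generators for planted-block synthetic fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
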