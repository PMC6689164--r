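Package: starmaps
Title: Similarity Testing for Accordant and Reproducible Microbiome
    Abundance Patterns
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tests whether the between-group difference pattern observed in
    one microbiome taxon-abundance dataset is reproduced in a second,
    independently generated dataset (STARMAPs). Count tables are converted to
    strictly positive compositions with Monte Carlo Dirichlet point estimates,
    mapped to Euclidean space with the isometric log-ratio transform, and
    compared in a shared principal-component space fitted on the first
    dataset only. Similarity is called by an intersection-union omnibus test
    combining PERMANOVA of each dataset's group segregation, a
    taxon-matching permutation test, and a bootstrap test on the cosine of
    the angle between the two group-difference directions. A multinomial
    simulation framework with known similar and dissimilar pairs measures
    sensitivity, specificity and ROC performance of the call.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    biomformat,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
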