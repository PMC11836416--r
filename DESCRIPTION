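Package: vagitools
Title: Population-Scale Vaginal Microbiome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible analysis chain for population-scale vaginal
    microbiome studies: ASV/taxon count-table filtering and rarefaction,
    alpha/beta diversity with permutation-based variance partitioning
    (PERMANOVA, ANOSIM, MRPP, db-RDA), covariate-adjusted per-taxon linear
    association with FDR control, SparCC compositional correlation networks
    with module detection and Zi/Pi node-role taxonomy, non-negative matrix
    factorization based community typing ("Vagitypes") with Yue-Clayton
    theta nearest-centroid classification, counterfactual mediation analysis
    with bootstrap inference and sensitivity analysis, and Firth-penalized
    logistic regression of reproductive outcomes. A seeded synthetic-cohort
    generator emulating Dirichlet-multinomial vaginal community types makes
    every stage testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    ape,
    phangorn,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phyloseq,
    mclust,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
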