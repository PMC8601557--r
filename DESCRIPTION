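Package: gutbalance
Title: Paired Gut Microbiome Analysis with Co-Abundance Networks and
    Microbial Balance Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis of paired (pre/post intervention) gut microbiome
    relative-abundance profiles: alpha and Bray-Curtis beta diversity with
    PERMANOVA, paired Wilcoxon differential abundance with
    Benjamini-Hochberg correction, SparCC basis-correlation co-abundance
    networks with permutation pseudo p-values and sign-flip edge
    extraction, covariate-adjusted partial Spearman screens against lung
    function and cardiopulmonary exercise testing parameters, and
    cross-validated forward selection of log-contrast microbial balances
    predicting continuous, dichotomous and survival-as-continuous
    responses. Includes a synthetic compositional data generator with
    planted effects so every stage has a ground-truth recovery test.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    MASS,
    vegan,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'balance.R'
    'differential.R'
    'diversity.R'
    'gutbalance-package.R'
    'io.R'
    'partial-correlation.R'
    'pipeline.R'
    'sparcc.R'
    'synthetic.R'
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
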