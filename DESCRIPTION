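Package: mbtree
Title: Phylogeny-Aware Modeling and Regression for Microbiome Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate modeling of microbiome count data with Dirichlet-tree
    multinomial (DTM) distributions, including covariate regression through a log
    link and a zero-inflated extension fitted by EM; empirical-Bayes estimation of
    per-sample relative abundances under a (zero-inflated) Dirichlet-tree prior;
    and tree-guided multiscale penalized regressions of a phenotype on relative
    abundances: sparse log-contrast subcomposition selection (TASSO) and a
    tree-guided fused lasso on raw proportions. Includes synthetic-data
    generators (random trees, DTM counts, sparse log-contrast responses) used as
    the package's test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    biomformat,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
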