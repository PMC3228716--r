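Package: ryeassoc
Title: Candidate-Gene Association Mapping of Frost Tolerance in Winter Rye
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Q+K linear mixed-model association analysis for candidate-gene
    studies in gamete-capture designs, modelled on multi-platform frost
    tolerance phenotyping in winter rye. Provides allele-similarity kinship
    estimation from SSR markers with standardization and a positive
    semi-definite guarantee, a restricted maximum likelihood engine for
    Gaussian mixed models with iid, correlated intercept-trend and
    kinship-structured random effects (via cholesky-root embedding of the
    relationship matrix), single-site and within-gene haplotype association
    scans, gene-by-gene epistasis likelihood-ratio tests, variance-explained
    accounting, cross-platform concordance summaries, and a synthetic-cohort
    generator that reproduces the five-population testcross structure of the
    motivating study with stored ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    optparse
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
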