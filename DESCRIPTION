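Package: gsetint
Title: Gene-Set-Level Integration of Multi-Platform Genomic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-stage gene set analysis for studies that measure several
    genomic data types (for example expression and copy number) on the same
    samples. Stage I computes model-based gene-to-phenotype association
    scores as deviance differences from per-gene logistic (or Cox)
    regressions, either per data type or integratively across all platforms
    measuring a gene. Stage II applies competitive (Mann-Whitney) or
    self-contained (permutation-averaged signed-rank) gene set tests, and
    per-platform results can be combined meta-analytically by geometric-mean
    or minimum P-value. A spike-in simulation suite generates multi-platform
    null backbones with configurable correlation structure, calibrates
    spiked mean shifts through two-sample t-test power, and evaluates
    methods by top-k discoveries, ROC/AUC and exclusive-discovery fractions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
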