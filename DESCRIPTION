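Package: dhgs
Title: Genomic Selection and Flowering-Time Locus Mapping in Doubled-Haploid Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-genome prediction and locus discovery for biparental
    doubled-haploid (DH) populations, built around flowering time in
    Brassica napus. Provides a DH population simulator (Haldane map
    function, multi-environment phenotypes with genotype-by-environment
    interaction), genotype quality control with LD-based tag-SNP pruning,
    eight genomic-prediction models (ridge-regression BLUP, Bayesian
    LASSO, BayesA, BayesB, Gaussian-kernel RKHS regression,
    epsilon-insensitive support vector regression with linear and
    Gaussian kernels, and random forests), repeated k-fold
    cross-validation with shared folds, breeding-value estimation,
    random-forest importance screening of trait-associated SNPs with
    allelic-direction tests, pairwise-epistasis detection by
    multivariate adaptive regression splines, and window-based
    functional-enrichment scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    ranger,
    e1071,
    jsonlite,
    yaml,
    rlang
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
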