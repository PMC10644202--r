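Package: progenyGS
Title: Genomic Prediction Benchmarking for Open-Pollinated Progeny Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for comparing genomic
    prediction methods in half-sib forest progeny trials. Provides a
    synthetic-data generator for open-pollinated families with linkage
    disequilibrium, additive and epistatic trait architectures and
    spatial micro-environment effects; VCF-based genotype quality
    control (missingness, minor allele frequency, exact Hardy-Weinberg
    test, distance thinning), PCA and linkage-disequilibrium decay
    estimation; tensor-product spline spatial adjustment of field
    phenotypes with iterative Grubbs outlier removal; Gibbs samplers
    for the Bayesian alphabet (BRR, BayesA, BayesB, BayesC, Bayesian
    LASSO); GBLUP and reproducing kernel Hilbert space regression on
    VanRaden and Gaussian kernels; a mixed-model association scan with
    kinship and principal-component correction for marker subset
    selection; random forest, gradient boosting and convolutional
    network baselines with inner cross-validation tuning; and a
    cross-validated benchmark comparing the predictive ability of all
    twelve model families.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    mgcv,
    jsonlite,
    Rcpp,
    VariantAnnotation,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
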