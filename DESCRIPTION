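Package: facemod
Title: Hierarchical Facial Shape Phenotyping and Gene-Based Multivariate
    Kernel Association Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the influence of low-frequency coding
    variants on multivariate three-dimensional facial shape. Implements
    global-to-local shape phenotyping from dense homologous landmarks
    (generalized Procrustes analysis, RV-coefficient spectral segmentation
    into a hierarchy of facial modules, per-module principal components with
    parallel analysis retention, covariate residualization, robust outlier
    screening), gene-based multivariate kernel association tests with
    SKAT/burden genotype kernels and homogeneous/heterogeneous phenotype
    kernels combined through a copula-based minimum-p omnibus, reverse
    ordinal regression single-variant follow-up, effective-number-of-tests
    multiplicity correction, and carrier/non-carrier effect-size and morph
    reporting. Includes a synthetic cohort generator emulating the data
    structure the analysis assumes, so the full pipeline is testable without
    access to controlled human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    mvtnorm,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
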