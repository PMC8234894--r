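Package: singlestep
Title: Single-Step Genomic BLUP with Iterative SNP Weighting and LR Cross-Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genetic and genomic evaluation of small livestock
    populations with the animal model. Implements pedigree relationship
    algebra (inbreeding by the Meuwissen-Luo recursion, Henderson's sparse
    inverse of the numerator relationship matrix, genotyped-subset blocks by
    Colleau's indirect method), the VanRaden genomic relationship matrix with
    tuning and blending to the pedigree base, the single-step H-inverse,
    sparse solvers for Henderson's mixed-model equations, iteratively
    weighted single-step GBLUP with nonlinearA SNP shrinkage, Gibbs sampling
    of variance components (univariate and multi-trait), LR-method
    cross-validation statistics (bias, dispersion, accuracy, reliability,
    genomic accuracy gain), and a gene-dropping simulator of pedigrees,
    genotypes, and correlated traits with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
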