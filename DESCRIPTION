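Package: smokesub
Title: Partitioning Genetic Liability to Smoking via GWAS-by-Subtraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Summary-statistics pipeline that partitions the genetic liability
    to lifetime smoking into an educational-attainment (EA) component and a
    direct "smoking-without-EA" component. Implements per-SNP association
    scans with Hardy-Weinberg/MAF/call-rate quality control, LD score
    regression for SNP-heritability and genetic correlation, a genome-wide
    mediation path estimator with per-SNP subtraction and delta-method
    standard errors, greedy p-value/LD/distance clumping, SBLUP ridge
    shrinkage of marginal effects for polygenic scoring, and a polygenic
    score by neighborhood-environment regression ladder with Keller
    interaction covariates, exchangeable GEE for family clustering,
    gene-environment correlation checks, stochastic-regression multiple
    imputation with Rubin pooling, and Bonferroni control. A seeded synthetic
    cohort generator with blockwise LD, liability-threshold smoking,
    mediation through EA, gene-environment correlation and optional
    interaction makes every stage testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    sandwich,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
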