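Package: pyramidqtl
Title: Integrative Pyramid Analysis Linking SNPs, miRNA and mRNA Expression to
    Drug-Sensitivity Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A six-stage integrative association framework ("pyramid analysis")
    that links SNP genotypes, miRNA expression, mRNA expression and a
    growth-independent drug-sensitivity phenotype in a sequential filtering
    design, together with a permutation-based empirical false discovery rate
    that preserves the full filtering pipeline under trait permutation.
    Includes construction of drug-specific phenotypes by residualizing log2
    IC50 on intrinsic cellular growth rate, a vectorized linear-association
    engine shared by all stages, comparison against traditional and
    eQTL-filtered genome-wide scans, and a synthetic-data generator with
    planted SNP to miRNA to mRNA to trait causal chains for calibration and
    power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
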