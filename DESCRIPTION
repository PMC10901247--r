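Package: mrscreen
Title: Bidirectional Two-Sample Mendelian Randomization Screening
Version: 0.1.0
Authors@R: person("mrscreen", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for bidirectional two-sample Mendelian
    randomization between many exposure traits (for example gut-microbiota
    taxon abundances) and an outcome trait, from GWAS summary statistics.
    Covers instrument selection (significance, minor-allele-frequency,
    greedy LD clumping, weak-instrument F filtering), allele harmonization
    with palindromic-SNP handling, the Wald ratio, inverse-variance
    weighted, MR-Egger and weighted-median estimators, and a sensitivity
    suite (Cochran's Q, MR-PRESSO global and outlier tests with iterative
    removal, leave-one-out, Steiger directionality, per-SNP F statistics).
    Includes a synthetic GWAS summary-statistics generator with known
    causal structure, pleiotropy, LD blocks and palindromic alleles so
    every stage is verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
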