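Package: mrkit
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) at the
    summary-statistic level: reading and validating per-SNP GWAS summary
    tables, instrument selection by p-value threshold, proxy substitution,
    allele harmonization (swaps, strand flips, palindromic arbitration by
    allele frequency), Wald-ratio and inverse-variance weighted causal
    estimation with weighted-median and MR-Egger sensitivity estimators,
    Cochran's Q heterogeneity and Egger-intercept pleiotropy tests,
    leave-one-out and plot-data diagnostics, Bonferroni-tiered inference
    across an exposure-by-outcome design, and a seeded synthetic instrument
    generator with an estimator benchmark so the whole pipeline is testable
    without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
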