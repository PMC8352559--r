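Package: mrkit
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization with GWAS summary
    statistics: instrument selection at genome-wide significance, greedy LD
    pruning, allele harmonization with palindromic-SNP handling, instrument
    strength diagnostics (variance explained, F statistics, binary-outcome
    power and detectable odds ratio), causal estimation (Wald ratios,
    inverse-variance-weighted, weighted median, MR-Egger), and sensitivity
    analysis (Cochran's Q, leave-one-out, MR-PRESSO global and outlier
    tests, confounder-driven instrument exclusion). Includes a seeded
    generator of synthetic two-sample summary statistics with known ground
    truth and a one-command pipeline producing tabular and JSON reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
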