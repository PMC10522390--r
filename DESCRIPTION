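Package: gwasMR
Title: Bidirectional Multivariable Two-Sample Mendelian Randomization
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Two-sample Mendelian randomization from GWAS summary
    statistics. Implements the full analysis chain: reading and validating
    summary-statistics tables, five-step instrument selection (locus-wide
    significance, LD clumping, allele-frequency and palindrome exclusion,
    outcome-association removal with proxy substitution, F-statistic
    screening), allele harmonization, five causal estimators
    (inverse-variance weighted, maximum likelihood, weighted median,
    MR-Egger, robust adjusted profile score), heterogeneity and
    horizontal-pleiotropy diagnostics (Cochran's Q, Egger intercept,
    MR-PRESSO global and outlier tests, leave-one-out), reverse and
    multivariable MR, Storey q-value multiple-testing correction with
    significance classification, and a synthetic GWAS summary-statistics
    generator with known ground truth so every stage can be verified
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
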