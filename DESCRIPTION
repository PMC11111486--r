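Package: mrcausal
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization workflow for
    GWAS summary statistics: reading and validation of association tables,
    allele harmonization with palindromic-variant resolution, instrument
    screening (genome-wide significance, LD clumping, minor-allele-frequency
    and F-statistic filters, Steiger directionality), five causal estimators
    (inverse-variance weighted with fixed and multiplicative random effects,
    MR-Egger regression, weighted median, simple and weighted mode), and
    sensitivity analyses (Cochran's Q heterogeneity, Egger intercept
    pleiotropy test, leave-one-out). Includes a seeded generator of synthetic
    two-sample GWAS summary statistics with known causal effect, pleiotropy
    and LD structure for validation and power studies, and a packaged table
    of ischemic-stroke instruments from the MEGASTROKE consortium.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, MASS
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
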