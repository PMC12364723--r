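Package: medimr
Title: Two-Sample, Multivariable and Mediation Mendelian Randomization
    with SMR-HEIDI Gene Prioritisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for causal inference on GWAS summary statistics:
    instrument selection (p-value threshold, greedy LD clumping,
    F-statistic filter), allele harmonization with palindromic-SNP
    removal, two-sample Mendelian randomization estimators (Wald ratio,
    inverse-variance weighted with multiplicative random effects,
    MR-Egger, weighted median, multivariable IVW), Cochran's Q,
    MR-PRESSO global/outlier/distortion tests, two-step mediation with
    proportion mediated and reverse-MR screening, summary-data-based MR
    (SMR) with the HEIDI heterogeneity test for eQTL colocalization-style
    gene prioritisation, nearest-gene annotation, and a synthetic
    summary-statistics generator with known ground truth for calibration
    and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
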