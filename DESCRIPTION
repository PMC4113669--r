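Package: vigorclass
Title: Genome-Enabled Classification of Binary Traits via Liability-Threshold G-BLUP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic prediction pipeline for binary (binomial) traits in
    line-structured plant populations, built around sugar-beet root vigor as
    the motivating case. Provides genotype quality control (duplicate,
    call-rate and minor-allele-frequency editing), VanRaden genomic
    relationship matrices, a liability-threshold G-BLUP classifier with
    logistic residuals fitted by Laplace-approximate maximum marginal
    likelihood, repeated k-fold cross-validated classification error,
    liability-scale heritability estimation with a fixed-heritability
    sensitivity mode, single-SNP logistic association scans, linkage
    disequilibrium summaries, LD-based genotype imputation with a masking
    (accuracy-curve) experiment, and a synthetic-population generator that
    emulates the study design for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
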