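Package: crossprot
Title: Cross-Platform Conserved Serum-Proteomics Signatures of Extreme Old Age
Version: 0.1.0
Authors@R: person("Maintainer", "Packaged", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for identifying serum proteins whose
    association with extreme old age is conserved across an LC-MS/MS
    (TMT isobaric label) study and an aptamer-array (SomaScan-style) study.
    Includes platform-specific preprocessing (depleted-protein removal,
    missingness QC by logistic GEE, three 20-percent missingness filters,
    uniform imputation, peptide-to-protein aggregation, trimmed-mean
    normalization, empirical-Bayes batch correction; aptamer log2 transform
    and 3-SD outlier masking), per-platform differential testing (linear GEE
    with clustered triplicates; OLS with global F-tests), the adjusted
    maximum-p-value (AdjMaxP) cross-platform conservation test with an
    effective-number-of-studies correction and pooled FDR, a kinship-aware
    linear mixed model for age-associated transcripts with concordance
    testing, hypergeometric gene-set over-representation analysis, and a
    synthetic-data generator with known ground truth for calibration and
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
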