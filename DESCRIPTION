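Package: somamosaic
Title: Low-VAF Somatic Mosaicism Analysis for Deep Exome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting and characterising low variant-allele-fraction
    somatic mosaic single-nucleotide variants in deep (several-hundred-fold)
    exome sequencing of brain and blood. Implements an empirical-Bayes
    beta-binomial error model fitted to a panel of normals with -log10 tail
    scores, ROC/Youden cutoff calibration, a reason-coded post-filter stack,
    exact-binomial validation against amplicon background error rates,
    per-subject mutation-burden summaries with age-accumulation rate
    regression and genome extrapolation, 96-channel mutational-signature
    refitting by multinomial maximum likelihood with BIC model selection,
    consequence classification with rare/deleterious prioritisation,
    permutation gene-set enrichment with a hypergeometric oracle and optional
    gene-length adjustment, and APOE/germline-risk carrier classification.
    A synthetic-cohort generator reproduces the count structure these stages
    assume so the whole pipeline is testable without sequence data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
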