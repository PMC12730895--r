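Package: motiscore
Title: Multi-Omics Tumor Immunogenicity Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates a transparent multi-omics tumor
    immunogenicity score for immune checkpoint inhibitor (ICI) outcome
    prediction. Derives per-sample biomarkers from pre-computed somatic
    variant, copy-number, TCR clonotype, neoantigen-candidate, HLA
    genotype and gene-expression tables (tumor mutation burden,
    neoantigen burden, TCR repertoire Shannon entropy, ICI
    resistance/response flags, HLA evolutionary divergence, immune gene
    expression); selects informative biomarkers by Fisher's exact and
    Mann-Whitney U tests with Spearman correlation pruning; combines
    them as a weighted sum of z-scores with weights proportional to
    -log10 selection p-values; and evaluates the score by ROC/AUC with
    Youden cutoff, Kaplan-Meier curves, and univariate Cox regression.
    Includes a seeded synthetic-cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
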