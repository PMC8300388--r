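Package: panelprune
Title: Marker Pruning Strategies and Marker-Density Effects on Genomic Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Construct SNP panels from high-density genotype data by
    physical-distance, linkage-disequilibrium and random pruning; compute
    marker-density measurements (mean and variance of adjacent physical
    gaps and of adjacent-pair r2); fit GBLUP with a VanRaden genomic
    relationship matrix and AI-REML variance components; evaluate panels
    by repeated k-fold cross-validation of genomic breeding-value
    accuracy; and run pooled within-level-standardized correlation
    analyses relating density measurements to accuracy. Includes native
    PLINK v1 binary genotype input/output and a seedable genotype and
    trait simulator with distance-decaying linkage disequilibrium so the
    whole pipeline runs reproducibly without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
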