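Package: omicbv
Title: Transcriptomic and Genomic Prediction of Family Breeding Values
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for predicting family breeding values from
    replicate-level RNA-seq transcript counts and family-level SNP dosages.
    Implements family-mean log2 aggregation of counts, batch-effect filtering
    of transcripts and SNPs by one-way ANOVA with local false-discovery-rate
    adjustment, relative-variance and greedy correlation-pruning feature
    screens, phenotype-association screens, Pearson similarity matrices and
    the VanRaden genomic relationship matrix, kriging (similarity-matrix
    BLUP) prediction, elastic-net regression by coordinate descent with
    bootstrap grid tuning, cross-batch train/test evaluation, and a
    synthetic-data generator emulating the multi-batch family design for
    validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
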