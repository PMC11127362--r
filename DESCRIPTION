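Package: prebioresponse
Title: Prebiotic Responder Phenotyping from In Vitro Fermentation Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An analysis pipeline for discovering prebiotic-specific
    carbohydrate gene clusters (CGCs) from in vitro fecal fermentation
    metagenomes and predicting prebiotic responder phenotypes before an
    intervention. Implements short-chain fatty acid (SCFA) based
    responder/non-responder phenotyping with Dunnett many-to-one contrasts,
    CGC detection from CAZyme/transporter annotation tables, substrate-specific
    gene filtering, negative-binomial Wald differential abundance with
    median-of-ratios normalization, qPCR absolute quantification via standard
    curves, RBF-SVM classifiers with permutation feature importance, and
    feeding-trial evaluation utilities (stratification, paired tests, Shannon
    diversity, Bray-Curtis PCoA). A synthetic-cohort generator with planted
    ground truth makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    mvtnorm,
    pracma,
    kernlab,
    jsonlite,
    tibble,
    vegan,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    pROC,
    DESeq2,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
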