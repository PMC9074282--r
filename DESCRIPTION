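Package: gxetrans
Title: Genetic Variation in the Transcriptional Response to a Developmental
    Exposure in Inbred Line Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for dissecting genotype-by-environment
    interaction in gene expression across a panel of inbred lines (a
    DGRP-style design), with a matched behavioural read-out. Fits balanced
    factorial mixed-model ANOVAs per transcript with expected-mean-square
    F tests, estimates variance components and broad-sense heritability,
    computes per-line delta-expression (exposed minus control line means),
    builds sex-specific delta-expression Pearson correlation networks with
    dual FDR/top-quantile edge filtering and MCODE modularisation, maps
    response eQTLs with permutation-based empirical FDR and forward
    conditional model selection, integrates eQTL-derived gene pairs with
    known-interaction databases and tests GO term overrepresentation, and
    derives activity and sleep phenotypes from Drosophila Activity Monitor
    files. A synthetic-data generator with full ground truth supports
    parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    ape,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    MASS,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
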