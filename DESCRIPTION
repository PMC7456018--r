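Package: panelforge
Title: Machine-Learning-Guided Design of Targeted cfDNA Sequencing Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs hybrid-capture sequencing panels for tumor variant
    detection in cell-free DNA (cfDNA). Somatic mutations from a tumor
    cohort are split into low-burden and high-burden classes by donor
    mutational burden, a class-weighted linear support vector classifier is
    trained on per-mutation feature annotations with cross-validated
    drop-one feature selection, and all mutations are ranked by signed
    distance from the classification hyperplane. Ranking scores are
    corrected for gene-length bias by within-length-bin standardization,
    the top-ranked mutations are expanded into merged probe intervals, and
    panels are evaluated by in-silico capture against multi-focus somatic
    variant call sets and by cfDNA tumor-variant screening filters. A
    synthetic-cohort simulator with planted feature signal supports
    end-to-end testing without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    stringr,
    jsonlite,
    generics,
    withr,
    stats,
    utils,
    pROC,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
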