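Package: tfconcord
Title: Ranked Transcription-Factor Target Repositories, Enrichment, and
    Kernel-Set Concordance Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with evidence-ranked transcription factor (TF)
    to target gene (TG) interaction tables: parsing, merging and querying the
    flat-file dialect used by curated interaction repositories; identifying
    modulated TFs in differential-expression gene lists by upper-tail
    hypergeometric enrichment with Bonferroni correction; assembling temporal
    transcriptional-cascade networks from time-course DE sets; and predicting
    novel context-specific TF targets by kernel-set concordance (KSC) -- a
    threshold-relaxation clustering of the TF's differentially expressed
    known targets followed by permutation-calibrated scoring of candidate
    genes against cluster centroids, with leave-one-out cross-validation and
    resampled-negative ROC/AUC evaluation. Includes seeded synthetic-data
    generators with planted co-expression structure so every pipeline stage
    can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    fgsea,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
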