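Package: omicstack
Title: Coordinated Containers for Multiple Omic Datasets on Overlapping Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A container data model for studies that assay overlapping (but not
    necessarily identical) sets of samples on several omic platforms. An
    'omicstack' multiset keeps one annotated dataset per experiment -- assay
    layers, per-dataset sample annotation, feature annotation and optional
    genomic feature ranges -- together with a reconstruction recipe so the
    original dataset can be recovered after any amount of container-level
    subsetting. Subsetting verbs cover union-style sample selection,
    complete-case intersection, dataset selection, genomic-range queries and
    safe feature/phenotype predicates. Typed ingestion functions validate
    expression, methylation and SNP data; a proteome extension handles values
    outside the limit of detection; and a methylation-expression correlation
    stage pairs CpGs with nearby expression features and reports
    covariate-adjusted association statistics. Ships a deterministic synthetic
    fixture generator, a directory-bundle serialization and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
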