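Package: lncraft
Title: Classification of Long Non-Coding and Transposon-Derived Transcripts
    in Reannotated Plant Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for curating a reference-guided transcriptome
    reannotation and classifying its transcripts, modelled on total
    RNA-Seq analyses of the maize leaf transcriptome. Implements
    post-assembly annotation curation (duplicate-reference merging,
    minimum-length filtering, class-code renaming, clustering of nearby
    monoexonic intergenic fragments), a threshold-and-homology decision
    tree separating coding transcripts from potential long non-coding
    RNAs, subclassification of non-coding transcripts into small-RNA
    precursors, transposon-derived transcripts and truly long non-coding
    RNAs, partitioning of lncRNAs into natural antisense transcripts and
    long intergenic non-coding RNAs, best-hit transposable-element
    classification with a dual confidence scheme, and filtering and
    cross-tabulation of differential-expression tables. A self-contained
    seed-and-extend local-similarity search with Karlin-Altschul
    statistics backs every homology step, and a synthetic-data generator
    with planted ground truth makes the whole pipeline testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    Biostrings,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
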