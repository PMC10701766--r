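Package: sescape
Title: Super-Enhancer Landscapes and Cooperative Enhancer Hierarchies from
    H3K27ac ChIP-Seq Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of H3K27ac ChIP-seq peak calls in tumor
    cohorts: consensus occupancy across samples, ROSE-style super-enhancer
    calling (12.5 kb stitching, input-normalized signal ranking, inflection
    cutoff), classification of genes by the number of converging classical
    enhancers (cooperative enhancers), two-step upstream transcription-factor
    inference combining regulon over-representation with position-weight-matrix
    scanning against a shuffled-genome background null, and closing statistics
    (expression hierarchy across regulatory-element classes, clinical 2x2
    Fisher tests, correlation-based sample clustering).  A fully synthetic
    cohort generator with planted ground truth supports parameter-recovery
    testing without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
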