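Package: mimpower
Title: Single- and Multiple-Trait Interval Mapping Power Studies for
    Correlated Seed-Composition Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates recombinant inbred line (RIL) populations carrying
    pleiotropic quantitative trait loci (QTL) for correlated seed oil and
    protein contents, and compares single-trait and joint multiple-trait
    multiple interval mapping (ST-MIM vs MT-MIM) at controlled
    heritabilities.  Provides a marker-to-marker meiosis simulator with
    Haldane and Kosambi map functions, hidden-Markov genotype
    probabilities on a cM grid, Haley-Knott single- and joint-trait LOD
    scans, genome-wide permutation thresholds with coupled resampling,
    forward-selection multiple-QTL models with 1.5-LOD support intervals
    and drop-one variance explained, and a replicated power study that
    scores per-QTL detection probabilities.  Also implements entry-mean
    broad-sense heritability and partial genetic correlation from
    balanced multi-environment trials, and capped (NOPA) versus uncapped
    (HY+Q) estimated processed values per bushel of soybean.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
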