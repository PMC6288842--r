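Package: whitemap
Title: F1 Outbred-Cross Linkage Mapping and Salmonid Synteny Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds sex-specific and sex-averaged genetic linkage maps from an
    F1 outbred cross genotyped at biallelic SNPs (pseudo-testcross design), and
    relates the resulting linkage groups to a duplicated reference genome. The
    pipeline covers informative-marker filtering (segregation typing, RAD-locus
    thinning, missingness and segregation-distortion filters), two-point
    recombination-fraction and LOD estimation, LOD-threshold linkage-group
    formation, heuristic marker ordering with restarts, Haldane map distances,
    map summary statistics including female:male recombination ratios, and a
    rediploidization-aware synteny analysis (majority-hit homolog assignment
    and an expected/observed per-arm mapping ratio contrasted between AORe and
    LORe chromosome arms with a Wilcoxon rank-sum test). A fully seeded
    synthetic-cross simulator with known truth makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
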