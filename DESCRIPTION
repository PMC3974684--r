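Package: replilife
Title: Replica-Set Survival Analysis and Regulatory Target Overlap for
    Nematode Longevity Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical machinery for cross-sectional ("replica set")
    lifespan and stress-survival assays in Caenorhabditis elegans and
    similar model systems: maximum-likelihood fitting of the
    two-parameter logit survival curve p(t) = 1/(1 + exp(a*t - b)) by
    iteratively reweighted least squares, LD50 (= b/a) and fitted-curve
    maximum lifespan (5% crossing), nonparametric bootstrap confidence
    intervals, label-swap permutation tests, and ratio-of-LD50
    comparisons across genetic backgrounds.  Also provides Kaplan-Meier
    and Mantel-Cox log-rank analysis for traditional longitudinal
    assays, a ChIP-seq promoter-target pipeline (strand-aware
    peak-midpoint-to-TSS profiling, -700/+100 window target assignment,
    E-box motif scanning, three-way target-set overlap, chi-squared GO
    enrichment), and seeded synthetic-data generators for every input.
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
    purrr,
    Rcpp,
    readr,
    rlang,
    S4Vectors,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
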