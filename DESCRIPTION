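Package: cnvchemo
Title: Gene-Family Copy Number, Sequence Characterization and
    Phylogenetically Corrected Chemotype Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for linking gene copy number of a tandemly duplicated
    synthase gene family to plant chemotype. Estimates per-gene copy number
    from whole-genome read depth scaled by expected single-copy coverage
    (including a collapsed-reference mode for total family copy number),
    characterizes the paralog family by pairwise distance, Nei-Gojobori
    dN/dS and premature-stop (truncation) detection, computes lineage-level
    copy-number statistics (one-way ANOVA, Tukey HSD post hoc, paired t),
    fits phylogenetic generalized least squares (Brownian motion) to
    correlate copy number with cannabinoid chemotype, and builds
    FPKM-normalized expression comparison tables. A synthetic-data module
    generates depth profiles with planted copy numbers, Yule trees with
    Brownian co-evolving traits, and codon pairs at controlled dN/dS, so
    every estimator can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
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
    tools,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
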