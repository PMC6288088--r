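Package: cooccurnet
Title: Compositional Co-Occurrence Networks and Interaction-Adjusted
    Similarity for Microbiome Count Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers taxon-taxon associations from genus-level amplicon
    count tables with the SparCC compositional correlation model, using
    Dirichlet posterior resampling of relative abundances, an iterative
    exclusion of extreme-covariance pairs from the log-ratio variation
    matrix, and permutation pseudo-p-values.  Builds thresholded
    co-occurrence networks with abundance, taxonomy and group-affinity
    node attributes, computes weighted Taxa INteraction-Adjusted (TINA)
    similarity between samples, ordinates samples by SMACOF
    stress-majorization multidimensional scaling, and reports per-sample
    Chao1 richness, coverage-adjusted (Chao-Shen) Shannon diversity and
    effective numbers of taxa.  Includes a synthetic-community generator
    with known basis correlations and group structure so every stage can
    be validated against a ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
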