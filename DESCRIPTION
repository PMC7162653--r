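Package: clonecircuits
Title: Lineage-Dependent Connectivity and Cell-Type Mapping in Cortical Clones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative machinery for analysing synaptic connectivity and
    transcriptomic identity of clonally related excitatory neurons in the
    neocortex. Implements a binomial cortical-cylinder model of the expected
    fraction of synaptic input arriving from clonally related cells with
    first-order (delta-method) error propagation; a lineage-pooling power
    analysis for two-proportion comparisons based on Cohen's h; connection
    probability estimation with exact Clopper-Pearson intervals, Fisher and
    chi-squared tests, distance-matched bootstrap controls, Laplace-smoothed
    log-ratio heatmaps and a binomial connectivity GLM; single-cell quality
    control, variable-gene selection, reference-atlas k-nearest-neighbour
    mapping with bootstrap precision, nearest-centroid cluster assignment and
    a permutation-calibrated region classifier; plus synthetic-data
    generators for clone populations, pair-test tables and clustered
    negative-binomial expression matrices so that every analysis is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    glmnet,
    Matrix,
    jsonlite,
    yaml,
    digest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
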