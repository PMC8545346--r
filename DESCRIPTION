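Package: resoclust
Title: Multi-Resolution Community Detection from Distance Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects communities in omics data from an arbitrary sample-by-sample
    (or feature-by-feature) distance matrix. A hierarchy is built by agglomerative
    clustering and descended top-down; branches are scored with a binary silhouette
    computed between sibling branches, and a branch is accepted as a community when
    it scores higher than both of its children, so cut levels adapt to the local
    resolution of the data. Detected communities receive resolution scores (harmonic
    mean of normalized size and cohesion) and optional metadata enrichment scores
    (modal-category frequency or normalized mutual information), used to rank the
    influence of covariates on the community structure. Includes a Gaussian-cluster
    benchmark simulator with controlled number, size, dimension, spacing and variance,
    pair-counting external validation indices (adjusted Rand, Jaccard,
    Fowlkes-Mallows, pairwise F1), principal coordinates ordination plots and
    tab-delimited reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    vegan,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
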