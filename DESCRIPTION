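Package: mdsmc
Title: Molecular Subclassification of Myelodysplastic Syndromes by Consensus Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised molecular subclassification of myelodysplastic
    syndromes (MDS) and secondary acute myeloid leukemia (sAML) from binary
    gene-mutation and karyotype profiles. Implements a linear autoencoder
    latent embedding of binary feature matrices, subsample consensus
    clustering with Gaussian-mixture components, silhouette-based selection
    of the number of clusters, cross-fold stability validation with the
    adjusted Rand index, cluster characterization by feature frequency and
    permutation importance, and survival-based aggregation of molecular
    clusters into risk groups (Kaplan-Meier, pairwise log-rank, Cox
    proportional hazards, Harrell's concordance). Includes a synthetic-cohort
    generator with planted latent-class structure so the full pipeline is
    exercisable without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    purrr,
    jsonlite,
    ranger,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
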