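Package: coughclust
Title: Deep Clustering with Autoencoder Embedding for Chronic Cough
    Patient Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stratifies coded-EMR patient cohorts by deep clustering with
    autoencoder embedding (DCAE): a sigmoid multilayer autoencoder is
    pretrained on bag-of-words term-frequency vectors over 3-digit ICD-10
    diagnosis categories, then refined jointly with a hard-assignment
    within-cluster distance objective so that the embedding and the cluster
    centers are optimized together. Includes the chronic-cough temporal
    labeling rule (three cough instances on separate visits within a 120-day
    window spanning at least eight weeks), classical comparison clusterers
    (PCA + k-means, hierarchical agglomerative, consensus, autoencoder +
    k-means, and the reconstruction-free ablation), purity and silhouette
    evaluation, per-cluster prevalence tables with chi-square comparisons,
    and a synthetic cohort generator with known latent subtypes so every
    component is testable without access to protected health records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
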