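# coughclust

Deep clustering with autoencoder embedding (DCAE) for stratifying
coded-EMR patient cohorts — built for the chronic cough problem, where no
ICD diagnosis code exists, cohorts must be assembled by a temporal rule
over coded cough encounters, and patient subtypes must be discovered
without labels.

`coughclust` is aimed at clinical informaticians and biostatisticians
working with long-format coded event extracts (patient id, date, ICD-10
code). It provides:

* the chronic-cough labeling rule: ≥ 3 cough instances on ≥ 3 separate
  visits within a 120-day window, first-to-last span ≥ 8 weeks;
* bag-of-words term-frequency features over 3-digit ICD-10 categories;
* the DCAE model and its comparison clusterers (PCA + k-means,
  hierarchical, consensus, autoencoder + k-means, and the
  reconstruction-free DC ablation);
* purity / silhouette / CC-dominated-cluster evaluation and an α sweep;
* per-cluster prevalence tables with pairwise chi-square tests against the
  non-CC reference cluster, and cohort demographic summaries;
* a synthetic cohort generator with known latent subtypes, so everything is
  testable without protected health records.

## The model

Patients are rows of a term-frequency matrix $X \in \mathbb{R}^{N\times d}$
over truncated ICD-10 categories. An encoder $f$ (fully connected layers of
1024, 512, 256 nodes; batch normalization before each sigmoid) embeds
$z_i = f(x_i)$, a mirrored decoder $g$ reconstructs $x_i' = g(z_i)$, and
training minimizes

$$L=\sum_{i=1}^{N}\sum_{j=1}^{K} I(z_i,\mu_j)\lVert z_i-\mu_j\rVert_2^2
+\alpha\sum_{i=1}^{N}\lVert x_i-x_i'\rVert_2^2,$$

where $I(z_i,\mu_j)$ indicates the nearest center and
$\mu_j = \tfrac{1}{|C_j|}\sum_{z_i\in C_j} z_i$. The autoencoder is
pretrained on mean squared reconstruction error (plus L1 weight
regularization), centers are initialized by k-means on the pretrained
embeddings, and embeddings and centers are then refined jointly by
mini-batch Adam alternating with hard reassignment. $\alpha = 0$ is the DC
ablation; with the network frozen the alternation is exactly Lloyd's
k-means, which anchors the package's correctness tests. The network is
implemented in plain R matrix arithmetic (manual backpropagation through
batch norm, Adam, L1), so there is no deep-learning framework dependency.

See `vignettes/chronic-cough-stratification.Rmd` for the methodology,
defaults, and design decisions.

## Worked example

```r
library(coughclust)

cohort <- generate_cohort(synthetic_spec(n_patients = 1000, seed = 7))
fm <- build_feature_matrix(cohort$events)
fm
#> feature_matrix: 1000 patients x 120 codes (total events 42997)

spec <- network_spec(ncol(fm$values), encoder_sizes = c(64, 32, 16))
fit <- train_dcae(fm, spec, training_config(n_clusters = 4, seed = 1))
fit$result
#> clustering_result: 1000 samples in 4 clusters
#> cluster
#>   1   2   3   4
#> 166 175 157 502

grp <- cohort$labels$group[match(fm$row_ids, cohort$labels$patient_id)]
cls <- cohort$labels$class[match(fm$row_ids, cohort$labels$patient_id)]
purity(fit$result$labels, grp)                                  # 0.991
silhouette_score(fit$result$embedding, fit$result$labels)       # 0.436
count_dominated_clusters(fit$result$labels, cls)                # 3
```

The synthetic cohort plants three CC subtypes plus controls; purity 0.991
against the latent groups means the four clusters recover that structure
almost exactly, the silhouette (0.436, Euclidean in the embedding) shows
well-separated clusters, and nCCD = 3 says three of the four clusters are
majority chronic cough. Characterization then names clusters and contrasts
category prevalences against the non-CC cluster:

```r
roles <- label_cluster_roles(fit$result$labels, cls)
rep <- prevalence_table(cohort$events, cohort$map,
                        data.frame(patient_id = fm$row_ids,
                                   cluster = fit$result$labels), roles)
writeLines(render_prevalence(rep))
#> | Category    | CC-2       | CC-1         | CC-3         | non-CC     | p value |
#> | Signature-1 | 0 (0%)     | 0 (0%)       | 156 (99.36%) | 0 (0%)     | < .0001 |
#> | Signature-3 | 165 (99.4%)| 0 (0%)       | 0 (0%)       | 0 (0%)     | < .0001 |
```

Each cell is `N (P%)`: patients in the cluster with at least one event in
the category; the p-value column holds the pairwise chi-square tests of
each CC cluster against the non-CC reference (`< .0001` when all agree).

`run_experiment()` / `compare_methods()` drive the same workflow across all
methods and a K grid from a YAML config, and `inst/cli/coughclust` exposes
`simulate`, `featurize`, `train`, `baseline`, `evaluate`, `characterize`,
`sweep-alpha`, and `compare` subcommands.

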