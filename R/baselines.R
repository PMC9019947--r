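#' Project onto principal components
#'
#' Centers the matrix and projects it onto its top `pca_dim` right singular
#' vectors. Used to bring all classical baselines to a common 256-dimensional
#' representation before clustering.
#'
#' @param X numeric matrix or `feature_matrix`.
#' @param pca_dim number of components to keep (capped at `min(N-1, d)`).
#' @return list with `scores` (N x pca_dim), `rotation`, `center`,
#'   `variances` (component variances, non-increasing).
#' @export
pca_project <- function(X, pca_dim = 256L) {
  X <- as_matrix_input(X)
  pca_dim <- min(pca_dim, ncol(X), nrow(X) - 1L)
  if (pca_dim < 1L) stop("need at least 2 rows for PCA", call. = FALSE)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr, "-")
  sv <- svd(Xc, nu = 0L, nv = pca_dim)
  scores <- Xc %*% sv$v
  list(scores = scores, rotation = sv$v, center = ctr,
       variances = sv$d[seq_len(pca_dim)]^2 / (nrow(X) - 1L))
}

# k-means++ seeding: first center uniform, subsequent centers drawn with
# probability proportional to squared distance to the nearest chosen center.
kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  chosen <- integer(K)
  chosen[1L] <- sample.int(n, 1L)
  if (K > 1L) {
    d2 <- drop(sqdist(X, X[chosen[1L], , drop = FALSE]))
    for (j in 2:K) {
      if (sum(d2) > 0) {
        chosen[j] <- sample.int(n, 1L, prob = d2)
      } else {
        chosen[j] <- sample(setdiff(seq_len(n), chosen[seq_len(j - 1L)]), 1L)
      }
      d2 <- pmin(d2, drop(sqdist(X, X[chosen[j], , drop = FALSE])))
    }
  }
  X[chosen, , drop = FALSE]
}

# Lloyd k-means from k-means++ seeds; retries seeding if initial centers
# coincide (stats::kmeans requires distinct starting centers).
seeded_kmeans <- function(X, K) {
  for (attempt in 1:10) {
    centers <- kmeanspp_centers(X, K)
    if (nrow(unique(centers)) == K) {
      return(suppressWarnings(
        stats::kmeans(X, centers = centers, algorithm = "Lloyd",
                      iter.max = 100L)))
    }
  }
  # duplicated data points: fall back to assignment by the distinct seeds
  list(cluster = assign_clusters(X, centers), centers = centers)
}

#' PCA + k-means baseline
#'
#' Reduces the feature matrix to `pca_dim` principal components, then runs
#' Lloyd's k-means from k-means++ seeds.
#'
#' @param X numeric matrix or `feature_matrix`.
#' @param K number of clusters (must not exceed N).
#' @param pca_dim PCA target dimensionality (default 256).
#' @param seed integer seed.
#' @return list with `labels` (1..K), `reduced` (the PCA scores), `centers`.
#' @export
kmeans_pca <- function(X, K, pca_dim = 256L, seed = 1L) {
  X <- as_matrix_input(X)
  if (K > nrow(X)) stop("K exceeds the number of samples", call. = FALSE)
  pr <- pca_project(X, pca_dim)
  km <- withr::with_seed(seed, seeded_kmeans(pr$scores, K))
  list(labels = as.integer(km$cluster), reduced = pr$scores,
       centers = km$centers, variances = pr$variances)
}

#' Hierarchical agglomerative clustering baseline
#'
#' Builds the agglomerative merge tree on Euclidean distances of the given
#' (usually PCA-reduced) representation and cuts it at K clusters. Ward
#' linkage by default; `single`, `complete`, and `average` are accepted.
#'
#' @param X_reduced numeric matrix (samples x features).
#' @param K number of clusters.
#' @param linkage linkage criterion (`"ward"`, `"single"`, `"complete"`,
#'   `"average"`).
#' @return list with `labels` and the `hclust` `tree`.
#' @export
hierarchical_clustering <- function(X_reduced, K, linkage = "ward") {
  X_reduced <- as_matrix_input(X_reduced)
  method <- switch(linkage,
                   ward = "ward.D2", single = "single",
                   complete = "complete", average = "average",
                   stop("unknown linkage: ", linkage, call. = FALSE))
  tree <- stats::hclust(stats::dist(X_reduced), method = method)
  list(labels = as.integer(stats::cutree(tree, k = K)), tree = tree)
}

#' Consensus clustering baseline
#'
#' Runs `H` k-means clusterings on random subsamples, accumulates the
#' consensus matrix `M[i, j] =` (times i, j co-clustered) / (times i, j
#' co-sampled), and derives final labels by average-linkage agglomerative
#' clustering of the dissimilarity `1 - M` cut at K. Pairs never sampled
#' together get consensus 0 (with a warning).
#'
#' @param X_reduced numeric matrix (usually the PCA representation).
#' @param K number of clusters (also used by the base k-means).
#' @param H number of resampling runs (>= 2).
#' @param subsample_fraction fraction of samples drawn per run, in (0, 1].
#' @param seed integer seed.
#' @return list with `labels` and the N x N `consensus` matrix.
#' @export
consensus_clustering <- function(X_reduced, K, H = 50L,
                                 subsample_fraction = 0.8, seed = 1L) {
  X_reduced <- as_matrix_input(X_reduced)
  if (H < 2L) stop("'H' must be >= 2", call. = FALSE)
  if (subsample_fraction <= 0 || subsample_fraction > 1) {
    stop("'subsample_fraction' must be in (0, 1]", call. = FALSE)
  }
  n <- nrow(X_reduced)
  m <- max(K, round(subsample_fraction * n))
  co_cluster <- matrix(0, n, n)
  co_sample <- matrix(0, n, n)
  withr::with_seed(seed, {
    for (h in seq_len(H)) {
      idx <- sort(sample.int(n, m))
      km <- seeded_kmeans(X_reduced[idx, , drop = FALSE], K)
      ind <- outer(km$cluster, km$cluster, "==") * 1
      co_cluster[idx, idx] <- co_cluster[idx, idx] + ind
      co_sample[idx, idx] <- co_sample[idx, idx] + 1
    }
  })
  never <- co_sample == 0
  if (any(never)) {
    warning(sum(never & upper.tri(never)),
            " sample pair(s) never co-sampled; consensus set to 0")
  }
  M <- ifelse(never, 0, co_cluster / pmax(co_sample, 1))
  diag(M) <- 1
  tree <- stats::hclust(stats::as.dist(1 - M), method = "average")
  list(labels = as.integer(stats::cutree(tree, k = K)), consensus = M)
}

#' Autoencoder + k-means baseline
#'
#' Pretrains the deep autoencoder for feature extraction (reconstruction
#' objective only; no joint refinement), then clusters the embeddings with
#' k-means.
#'
#' @param X numeric matrix or `feature_matrix`.
#' @param spec a [network_spec()].
#' @param config a [training_config()] (`n_clusters`, seed, epochs, ...).
#' @return list with `labels`, `embedding`, and the `autoencoder`.
#' @export
dae_kmeans <- function(X, spec = NULL, config = training_config()) {
  X <- as_matrix_input(X)
  ae <- pretrain_autoencoder(X, spec, config)
  Z <- encode(ae, X)
  km <- withr::with_seed(config$seed + 1L, seeded_kmeans(Z, config$n_clusters))
  list(labels = as.integer(km$cluster), embedding = Z, autoencoder = ae)
}

#' Reconstruction-free deep clustering ablation (DC)
#'
#' The DCAE variant that overlooks the reconstruction loss: identical code
#' path with `alpha = 0`, so only the within-cluster distance term shapes
#' the embedding during joint training.
#'
#' @inheritParams dae_kmeans
#' @return as [train_dcae()].
#' @export
dc_clustering <- function(X, spec = NULL, config = training_config()) {
  config$alpha <- 0
  train_dcae(X, spec, config)
}
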