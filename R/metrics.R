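#' Purity of a clustering against reference classes
#'
#' Each cluster is credited with its majority class:
#' `purity = (1/N) * sum_over_clusters max_class |cluster & class|`.
#' 1 means every cluster is single-class; the score is invariant to
#' permutations of cluster labels and class names.
#'
#' @param labels cluster labels (any atomic type).
#' @param classes reference classes (e.g. CC / non-CC, or latent subtype).
#' @return scalar in \[0, 1\].
#' @export
purity <- function(labels, classes) {
  if (length(labels) == 0 || length(labels) != length(classes)) {
    stop("'labels' and 'classes' must be non-empty and of equal length",
         call. = FALSE)
  }
  tab <- table(labels, classes)
  sum(apply(tab, 1L, max)) / length(labels)
}

#' Mean silhouette value of a clustering
#'
#' For each point, `a` is its mean distance to the other members of its own
#' cluster and `b` the smallest mean distance to any other cluster; the
#' silhouette is `(b - a) / max(a, b)`. Points in singleton clusters, and
#' degenerate points with `a = b = 0`, score 0. Distances are Euclidean in
#' the supplied representation (each method's own embedding, or the PCA
#' representation for the classical baselines). For cohorts above
#' `max_exact` points a seeded uniform subsample is scored instead.
#'
#' @param Z embedding matrix, or a `dist` object / full distance matrix.
#' @param labels cluster labels (>= 2 distinct values required).
#' @param max_exact largest N for which the exact O(N^2) score is computed.
#' @param seed seed for the subsample drawn when N > `max_exact`.
#' @return scalar in \[-1, 1\].
#' @export
silhouette_score <- function(Z, labels, max_exact = 20000L, seed = 1L) {
  if (inherits(Z, "dist")) {
    D <- as.matrix(Z)
  } else if (is.matrix(Z) && isSymmetric(unname(Z)) && nrow(Z) == length(labels) &&
             ncol(Z) == length(labels) && all(diag(Z) == 0)) {
    D <- Z
  } else {
    D <- NULL
  }
  n <- length(labels)
  if (length(unique(labels)) < 2L) {
    stop("silhouette is undefined for a single cluster", call. = FALSE)
  }
  if (is.null(D)) {
    Z <- as_matrix_input(Z)
    if (nrow(Z) != n) stop("'Z' and 'labels' lengths differ", call. = FALSE)
    if (n > max_exact) {
      keep <- withr::with_seed(seed, sort(sample.int(n, max_exact)))
      Z <- Z[keep, , drop = FALSE]
      labels <- labels[keep]
      if (length(unique(labels)) < 2L) {
        stop("subsample collapsed to a single cluster; raise 'max_exact'",
             call. = FALSE)
      }
      n <- max_exact
    }
    D <- as.matrix(stats::dist(Z))
  }
  f <- factor(labels)
  sizes <- as.vector(table(f))
  # n x K matrix of summed distances from each point to each cluster
  S <- t(rowsum(D, f))
  own <- cbind(seq_len(n), as.integer(f))
  a <- S[own] / pmax(sizes[as.integer(f)] - 1L, 1L)
  Mean <- sweep(S, 2L, sizes, "/")
  Mean[own] <- Inf
  b <- apply(Mean, 1L, min)
  s <- (b - a) / pmax(pmax(a, b), .Machine$double.eps)
  s[sizes[as.integer(f)] == 1L] <- 0
  s[a == 0 & b == 0] <- 0
  mean(s)
}

#' Count CC-dominated clusters (nCCD)
#'
#' A cluster is CC-dominated when strictly more than `threshold` (default
#' 50%) of its members belong to the positive class.
#'
#' @param labels cluster labels.
#' @param classes binary class per sample.
#' @param positive the value of `classes` counted as the positive (CC)
#'   class; defaults to `TRUE` for logical classes and `"CC"` otherwise.
#' @param threshold dominance threshold, strict inequality.
#' @return integer count of dominated clusters (<= number of clusters).
#' @export
count_dominated_clusters <- function(labels, classes, positive = NULL,
                                     threshold = 0.5) {
  if (length(labels) != length(classes)) stop("length mismatch", call. = FALSE)
  positive <- positive %||% if (is.logical(classes)) TRUE else "CC"
  frac <- tapply(classes == positive, labels, mean)
  sum(frac > threshold)
}

#' Sweep the clustering/reconstruction balance parameter
#'
#' Trains one DCAE per value of `alpha` (shared seed and data split) and
#' records purity and silhouette for each, reproducing the
#' balance-parameter analysis: `alpha` ranges over \[0, 1\] in steps of 0.1
#' by default, and the `alpha = 0` row is exactly the reconstruction-free DC
#' ablation.
#'
#' @param X numeric matrix or `feature_matrix`.
#' @param classes binary class per row (CC / non-CC or latent subtype), used
#'   for purity.
#' @param spec a [network_spec()].
#' @param config a [training_config()]; its `alpha` is overridden per sweep
#'   point.
#' @param alphas numeric vector of alpha values.
#' @param out_file optional path; when given the table is persisted as TSV.
#' @return data.frame with columns `alpha`, `purity`, `silhouette`.
#' @export
alpha_sweep <- function(X, classes, spec = NULL, config = training_config(),
                        alphas = seq(0, 1, by = 0.1), out_file = NULL) {
  rows <- lapply(alphas, function(a) {
    cfg <- config
    cfg$alpha <- a
    fit <- train_dcae(X, spec, cfg)
    data.frame(alpha = a,
               purity = purity(fit$result$labels, classes),
               silhouette = silhouette_score(fit$result$embedding,
                                             fit$result$labels))
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_file)) {
    write.table(out, out_file, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  out
}
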