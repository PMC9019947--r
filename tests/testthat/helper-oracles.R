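# Independent brute-force oracles, deliberately naive: each re-derives a
# quantity from its definition with plain loops so the vectorized package
# implementations can be checked against them.

brute_assign <- function(Z, centers) {
  vapply(seq_len(nrow(Z)), function(i) {
    d <- vapply(seq_len(nrow(centers)),
                function(j) sum((Z[i, ] - centers[j, ])^2), numeric(1))
    which(d == min(d))[1]
  }, integer(1))
}

brute_centers <- function(Z, labels, K) {
  out <- matrix(NA_real_, K, ncol(Z))
  for (j in seq_len(K)) {
    members <- Z[labels == j, , drop = FALSE]
    if (nrow(members) > 0) out[j, ] <- colMeans(members)
  }
  out
}

brute_silhouette <- function(Z, labels) {
  n <- nrow(Z)
  d <- function(i, j) sqrt(sum((Z[i, ] - Z[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(vapply(own, function(j) d(i, j), numeric(1)))
    b <- Inf
    for (k in setdiff(unique(labels), labels[i])) {
      others <- which(labels == k)
      b <- min(b, mean(vapply(others, function(j) d(i, j), numeric(1))))
    }
    s[i] <- if (a == 0 && b == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

brute_purity <- function(labels, classes) {
  total <- 0
  for (k in unique(labels)) {
    total <- total + max(table(classes[labels == k]))
  }
  total / length(labels)
}

# textbook Pearson statistic: sum over cells of (O - E)^2 / E
brute_chisq <- function(a, b, c, d) {
  O <- rbind(c(a, b), c(c, d))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  sum((O - E)^2 / E)
}

# within-cluster sum of squares of a partition
wss <- function(X, labels) {
  total <- 0
  for (k in unique(labels)) {
    M <- X[labels == k, , drop = FALSE]
    total <- total + sum(sweep(M, 2, colMeans(M))^2)
  }
  total
}

# minimal WSS over every 2-partition, by exhaustive enumeration
best_wss_2partition <- function(X) {
  n <- nrow(X)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    labels <- as.integer(intToBits(mask)[1:n]) + 1L
    if (length(unique(labels)) < 2) next
    best <- min(best, wss(X, labels))
  }
  best
}

# naive single-linkage agglomeration; returns the partition at each K
brute_single_linkage <- function(X) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  groups <- as.list(seq_len(n))
  partitions <- list()
  partitions[[n]] <- seq_len(n)
  while (length(groups) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (g1 in seq_along(groups)) for (g2 in seq_along(groups)) {
      if (g1 >= g2) next
      dmin <- min(D[groups[[g1]], groups[[g2]]])
      if (dmin < bestd) { bestd <- dmin; best <- c(g1, g2) }
    }
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
    labels <- integer(n)
    for (g in seq_along(groups)) labels[groups[[g]]] <- g
    partitions[[length(groups)]] <- labels
  }
  partitions
}

# two labelings describe the same partition (up to renaming)
same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}
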