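test_that("purity credits each cluster with its majority class", {
  expect_equal(purity(c(1, 1, 2, 2), c("CC", "CC", "non", "non")), 1)
  expect_equal(purity(c(1, 1, 1), c("CC", "CC", "non")), 2 / 3)
  expect_equal(purity(c(1, 1, 1, 2, 2, 2),
                      c("CC", "CC", "non", "non", "non", "CC")), 4 / 6)
  expect_error(purity(1:3, 1:2), "equal length")
})

test_that("purity is permutation invariant, bounded, and 1 on singletons", {
  set.seed(71)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    labels <- sample.int(5, n, replace = TRUE)
    classes <- sample(c("CC", "non-CC"), n, replace = TRUE)
    p <- purity(labels, classes)
    expect_gte(p, 0); expect_lte(p, 1)
    expect_equal(p, brute_purity(labels, classes))
    perm <- sample.int(5)
    expect_equal(purity(perm[labels], classes), p)
    relab <- c(CC = "x", `non-CC` = "y")[classes]
    expect_equal(purity(labels, relab), p)
    expect_equal(purity(seq_len(n), classes), 1)
  }
})

test_that("merging two clusters never increases purity", {
  set.seed(73)
  for (rep in 1:20) {
    n <- 40
    labels <- sample.int(4, n, replace = TRUE)
    classes <- sample(c("a", "b"), n, replace = TRUE)
    merged <- labels
    merged[merged == 2] <- 1
    expect_lte(purity(merged, classes), purity(labels, classes) + 1e-12)
  }
})

test_that("silhouette matches the brute-force pairwise definition", {
  Z <- matrix(c(0, 0.1, 10, 10.1), 4, 1)
  labels <- c(1, 1, 2, 2)
  expect_equal(silhouette_score(Z, labels), brute_silhouette(Z, labels))
  expect_equal(silhouette_score(Z, labels), 0.99, tolerance = 1e-3)
  # all points identical across two clusters: a = b = 0 convention
  expect_equal(silhouette_score(matrix(1, 4, 2), c(1, 1, 2, 2)), 0)
  set.seed(79)
  for (rep in 1:10) {
    n <- 30
    Zr <- matrix(rnorm(n * 3), n, 3)
    lr <- sample.int(4, n, replace = TRUE)
    expect_equal(silhouette_score(Zr, lr), brute_silhouette(Zr, lr),
                 tolerance = 1e-10)
  }
  expect_error(silhouette_score(Z, rep(1, 4)), "single cluster")
})

test_that("silhouette is bounded and invariant under isometries", {
  set.seed(83)
  Z <- matrix(rnorm(40 * 2), 40, 2)
  labels <- sample.int(3, 40, replace = TRUE)
  s <- silhouette_score(Z, labels)
  expect_gte(s, -1); expect_lte(s, 1)
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  expect_equal(silhouette_score(Z %*% R + 5, labels), s, tolerance = 1e-10)
  # accepts a precomputed distance object
  expect_equal(silhouette_score(dist(Z), labels), s, tolerance = 1e-10)
  # singleton clusters score zero
  Zs <- matrix(c(0, 0.1, 50), 3, 1)
  expect_equal(silhouette_score(Zs, c(1, 1, 2)),
               brute_silhouette(Zs, c(1, 1, 2)))
})

test_that("large cohorts are scored on a seeded subsample", {
  set.seed(89)
  Z <- matrix(rnorm(600 * 2), 600, 2)
  labels <- rep(1:2, 300)
  s1 <- silhouette_score(Z, labels, max_exact = 200, seed = 4)
  s2 <- silhouette_score(Z, labels, max_exact = 200, seed = 4)
  expect_identical(s1, s2)
  expect_gte(s1, -1); expect_lte(s1, 1)
})

test_that("dominated-cluster counting uses a strict majority", {
  cl <- c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2)
  cc <- c(rep("CC", 3), rep("non-CC", 2), rep("CC", 2), rep("non-CC", 3))
  expect_equal(count_dominated_clusters(cl, cc), 1)            # 60% vs 40%
  even <- c("CC", "non-CC")[rep(1:2, 5)]
  expect_equal(count_dominated_clusters(rep(1, 10), even), 0)  # exactly 50%
  expect_equal(count_dominated_clusters(cl, rep("CC", 10)), 2) # all pure
  expect_lte(count_dominated_clusters(cl, cc), length(unique(cl)))
  expect_equal(count_dominated_clusters(cl, cc == "CC"), 1)    # logical form
})

test_that("the alpha sweep reproduces the DC ablation at alpha = 0", {
  cohort <- small_cohort(n = 100)
  fm <- build_feature_matrix(cohort$events)
  grp <- cohort_groups(cohort, fm)
  spec <- tiny_spec(ncol(fm$values))
  cfg <- tiny_config(n_clusters = 4L)
  tab <- alpha_sweep(fm, grp, spec, cfg, alphas = c(0, 0.5))
  expect_equal(tab$alpha, c(0, 0.5))
  expect_true(all(c("purity", "silhouette") %in% names(tab)))
  dc <- dc_clustering(fm, spec, cfg)
  expect_equal(tab$purity[1], purity(dc$result$labels, grp))
  expect_equal(tab$silhouette[1],
               silhouette_score(dc$result$embedding, dc$result$labels))
  # default grid is the 11 values 0, 0.1, ..., 1
  expect_equal(eval(formals(alpha_sweep)$alphas), seq(0, 1, 0.1))
})
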