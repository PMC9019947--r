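test_that("nearest-center assignment matches exhaustive comparison", {
  Z <- matrix(c(0, 10), 2, 1)
  centers <- matrix(c(0, 10), 2, 1)
  expect_equal(assign_clusters(Z, centers), c(1L, 2L))
  # ties go to the lowest center index
  expect_equal(assign_clusters(matrix(5, 1, 1), centers), 1L)
  set.seed(17)
  Zr <- matrix(rnorm(40 * 3), 40, 3)
  Cr <- matrix(rnorm(3 * 3), 3, 3)
  expect_equal(assign_clusters(Zr, Cr), brute_assign(Zr, Cr))
  expect_error(assign_clusters(Zr, matrix(NA_real_, 2, 3)), "finite")
})

test_that("center update takes within-cluster means and re-seeds empties", {
  expect_equal(update_centers(matrix(c(1, 3), 2, 1), c(1L, 1L), 1L),
               matrix(2, 1, 1))
  # every point its own cluster: centers equal the points
  Z <- matrix(rnorm(12), 4, 3)
  expect_equal(update_centers(Z, 1:4, 4L), Z, ignore_attr = TRUE)
  set.seed(23)
  Zr <- matrix(rnorm(60 * 2), 60, 2)
  lr <- sample.int(4, 60, replace = TRUE)
  expect_equal(update_centers(Zr, lr, 4L), brute_centers(Zr, lr, 4L))
  # empty cluster 2 re-seeded at the point farthest from its current center
  cur <- matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)
  Zs <- matrix(c(0, 0, 1, 1, 2, 2), 3, 2, byrow = TRUE)
  up <- update_centers(Zs, c(1L, 1L, 1L), 2L, cur)
  expect_equal(up[2, ], c(0, 0))  # farthest from (5, 5)
  expect_error(update_centers(Zs, c(1L, 1L, 1L), 2L), "empty cluster")
})

test_that("joint loss decomposes into clustering and reconstruction terms", {
  Z <- matrix(c(0, 2), 2, 1)
  centers <- matrix(1, 1, 1)
  X <- matrix(rnorm(4), 2, 2)
  lo <- dcae_loss(X, X, Z, centers, c(1L, 1L), alpha = 0.7)
  expect_equal(lo$clustering, 2)   # (0-1)^2 + (2-1)^2
  expect_equal(lo$total, 2)        # perfect reconstruction for any alpha
  # alpha = 0 equals the clustering term to machine precision
  Xp <- X + matrix(runif(4), 2, 2)
  lo0 <- dcae_loss(X, Xp, Z, centers, c(1L, 1L), alpha = 0)
  expect_identical(lo0$total, lo0$clustering)
  # points exactly at their centers with perfect reconstruction: L = 0
  loz <- dcae_loss(X, X, centers[c(1, 1), , drop = FALSE], centers,
                   c(1L, 1L), alpha = 0.5)
  expect_equal(loz$total, 0)
  # unsquared reconstruction variant uses the plain L2 norm
  lou <- dcae_loss(X, Xp, Z, centers, c(1L, 1L), alpha = 1,
                   squared_recon = FALSE)
  expect_equal(lou$reconstruction, sum(sqrt(rowSums((X - Xp)^2))))
  expect_error(dcae_loss(X, Xp, Z, centers, c(1L, 1L), alpha = -0.1),
               "non-negative")
})

test_that("assign/update sweeps never increase the clustering term", {
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(20:200, 1)
    v <- sample(2:5, 1)
    K <- sample(2:5, 1)
    Z <- matrix(rnorm(n * v), n, v)
    centers <- Z[sample.int(n, K), , drop = FALSE]
    prev <- Inf
    for (it in 1:4) {
      labels <- assign_clusters(Z, centers)
      obj <- sum((Z - centers[labels, , drop = FALSE])^2)
      expect_lte(obj, prev + 1e-9)
      centers <- update_centers(Z, labels, K, centers)
      obj2 <- sum((Z - centers[labels, , drop = FALSE])^2)
      expect_lte(obj2, obj + 1e-9)
      prev <- obj2
    }
  }
})

test_that("frozen-network alternation equals reference Lloyd k-means", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(20:50, 1)
    K <- sample(2:3, 1)
    Z <- matrix(rnorm(n * 2), n, 2)
    init <- Z[sample.int(n, K), , drop = FALSE]
    # package path: alternate hard assignment and mean update to a fixed point
    centers <- init
    labels <- assign_clusters(Z, centers)
    for (it in 1:100) {
      centers <- update_centers(Z, labels, K, centers)
      new_labels <- assign_clusters(Z, centers)
      if (identical(new_labels, labels)) break
      labels <- new_labels
    }
    km <- suppressWarnings(stats::kmeans(Z, centers = init,
                                         algorithm = "Lloyd", iter.max = 200))
    expect_true(same_partition(labels, km$cluster))
  }
})

test_that("DCAE training is deterministic and its alpha = 0 path is DC", {
  cohort <- small_cohort(n = 120)
  fm <- build_feature_matrix(cohort$events)
  spec <- tiny_spec(ncol(fm$values))
  cfg <- tiny_config(n_clusters = 4L, alpha = 0)
  fit1 <- train_dcae(fm, spec, cfg)
  fit2 <- train_dcae(fm, spec, cfg)
  expect_identical(fit1$result$labels, fit2$result$labels)
  expect_identical(fit1$model$joint_history, fit2$model$joint_history)
  dc <- dc_clustering(fm, spec, tiny_config(n_clusters = 4L, alpha = 0.9))
  expect_identical(dc$result$labels, fit1$result$labels)
  expect_equal(dc$model$config$alpha, 0)
})

test_that("prediction reproduces training assignments definitionally", {
  cohort <- small_cohort(n = 100)
  fm <- build_feature_matrix(cohort$events)
  fit <- train_dcae(fm, tiny_spec(ncol(fm$values)), tiny_config())
  expect_identical(predict_clusters(fit$model, fm), fit$result$labels)
  # duplicated single row gets identical labels
  row2 <- fm$values[c(1, 1), , drop = FALSE]
  pred <- predict_clusters(fit$model, row2)
  expect_identical(pred[1], pred[2])
  expect_identical(predict_clusters(fit$model, fm),
                   assign_clusters(encode(fit$model, fm), fit$model$centers))
  expect_error(predict_clusters(fit$model, fm$values[, 1:3]), "expects")
})

test_that("training rejects more clusters than training rows", {
  X <- matrix(runif(20 * 5), 20, 5)
  expect_error(train_dcae(X, tiny_spec(5), tiny_config(n_clusters = 15L)),
               "exceeds")
})

test_that("a trained model survives the plain-text round trip", {
  cohort <- small_cohort(n = 80)
  fm <- build_feature_matrix(cohort$events)
  fit <- train_dcae(fm, tiny_spec(ncol(fm$values)), tiny_config())
  dir <- withr::local_tempdir()
  write_dcae_model(fit$model, dir)
  model2 <- read_dcae_model(dir)
  expect_equal(model2$centers, unname(fit$model$centers), tolerance = 1e-12)
  expect_identical(predict_clusters(model2, fm),
                   predict_clusters(fit$model, fm))
})
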