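#' Assign embedded samples to their nearest cluster center
#'
#' Hard assignment: sample i gets the label of the center with the smallest
#' squared Euclidean distance to its embedding; ties go to the lowest center
#' index.
#'
#' @param Z N x v embedding matrix.
#' @param centers K x v matrix of cluster centers.
#' @return integer vector of labels in `1..K`.
#' @export
assign_clusters <- function(Z, centers) {
  Z <- as_matrix_input(Z); centers <- as_matrix_input(centers)
  if (ncol(Z) != ncol(centers)) stop("Z and centers differ in dimension", call. = FALSE)
  if (!all(is.finite(centers))) stop("centers must be finite", call. = FALSE)
  max.col(-sqdist(Z, centers), ties.method = "first")
}

#' Recompute cluster centers as within-cluster means
#'
#' Each non-empty cluster's center becomes the arithmetic mean of its
#' members' embeddings. An empty cluster is re-seeded at the point farthest
#' from that cluster's current center (hence `centers` must be supplied when
#' empties can occur).
#'
#' @param Z N x v embedding matrix.
#' @param labels integer labels in `1..K`.
#' @param K number of clusters.
#' @param centers optional current K x v centers, used only to re-seed empty
#'   clusters.
#' @return K x v matrix of updated centers.
#' @export
update_centers <- function(Z, labels, K, centers = NULL) {
  Z <- as_matrix_input(Z)
  labels <- check_labels(labels, nrow(Z), K)
  sizes <- tabulate(labels, nbins = K)
  out <- matrix(NA_real_, K, ncol(Z))
  occupied <- sizes > 0L
  sums <- rowsum(Z, labels)
  out[sort(unique(labels)), ] <- sums / sizes[occupied]
  if (any(!occupied)) {
    if (is.null(centers)) {
      stop("empty cluster encountered and no current centers supplied", call. = FALSE)
    }
    for (j in which(!occupied)) {
      far <- which.max(sqdist(Z, centers[j, , drop = FALSE]))
      out[j, ] <- Z[far, ]
    }
  }
  out
}

#' Joint deep-clustering objective value
#'
#' `L = sum_i ||z_i - mu_{c(i)}||^2 + alpha * sum_i ||x_i - x'_i||^2`
#' where `c(i)` is the hard assignment of sample i. The reconstruction term
#' uses the squared L2 norm by default for consistency with the autoencoder
#' objective; `squared_recon = FALSE` gives the unsquared-norm variant.
#' With `alpha = 0` the value equals the clustering term exactly (the
#' reconstruction-free "DC" ablation objective).
#'
#' @param X,X_prime input and reconstruction matrices (N x d).
#' @param Z embedding matrix (N x v).
#' @param centers K x v cluster centers.
#' @param labels integer labels in `1..K` (consistent with
#'   [assign_clusters()]).
#' @param alpha non-negative reconstruction weight.
#' @param squared_recon use squared L2 norms in the reconstruction term.
#' @return list with `clustering`, `reconstruction`, and
#'   `total = clustering + alpha * reconstruction`.
#' @export
dcae_loss <- function(X, X_prime, Z, centers, labels, alpha,
                      squared_recon = TRUE) {
  if (alpha < 0) stop("'alpha' must be non-negative", call. = FALSE)
  X <- as_matrix_input(X); X_prime <- as_matrix_input(X_prime)
  Z <- as_matrix_input(Z); centers <- as_matrix_input(centers)
  if (!identical(dim(X), dim(X_prime))) stop("X / X_prime shape mismatch", call. = FALSE)
  labels <- check_labels(labels, nrow(Z), nrow(centers))
  clust <- sum((Z - centers[labels, , drop = FALSE])^2)
  sq <- rowSums((X - X_prime)^2)
  recon <- if (squared_recon) sum(sq) else sum(sqrt(sq))
  list(clustering = clust, reconstruction = recon,
       total = clust + alpha * recon)
}

#' Train the deep clustering model with autoencoder embedding
#'
#' The full procedure: (a) pretrain the autoencoder on the training half by
#' mean-squared reconstruction error; (b) initialize the K cluster centers
#' by k-means (20 restarts) on the pretrained embeddings; (c) for each joint
#' epoch, assign training samples to their nearest centers, update the
#' network by mini-batch Adam on the joint objective (clustering +
#' `alpha` x reconstruction, labels and centers held fixed within the
#' epoch), then recompute embeddings and move each center to the mean of its
#' members; (d) embed every sample -- training and held-out alike -- and
#' assign it to the nearest final center.
#'
#' With `learning_rate = 0` the network stays frozen after pretraining and
#' the alternation reduces exactly to Lloyd's k-means on the fixed
#' embeddings. With `alpha = 0` the reconstruction gradient is dropped (the
#' "DC" ablation).
#'
#' @param X numeric matrix or `feature_matrix` (patients x features).
#' @param spec a [network_spec()] (default: standard architecture for
#'   `ncol(X)`).
#' @param config a [training_config()]; `n_clusters` must not exceed the
#'   number of training rows.
#' @return list with `model` (class `dcae_model`: autoencoder, centers,
#'   config, loss history) and `result` (class `clustering_result`: per-row
#'   `labels`, `embedding`, `is_training`, `row_ids`).
#' @export
train_dcae <- function(X, spec = NULL, config = training_config()) {
  row_ids <- if (inherits(X, "feature_matrix")) X$row_ids else rownames(X)
  X <- as_matrix_input(X)
  spec <- spec %||% network_spec(ncol(X))
  n <- nrow(X)
  K <- config$n_clusters
  n_train <- max(1L, round(config$train_fraction * n))
  if (K > n_train) {
    stop(sprintf("n_clusters = %d exceeds the %d training rows", K, n_train),
         call. = FALSE)
  }

  withr::with_seed(config$seed, {
    train_idx <- sort(sample.int(n, n_train))
    scaling <- fit_scaling(X[train_idx, , drop = FALSE],
                           config$scaling %||% "global")
    Xs <- apply_scaling(X, scaling)
    Xtr <- Xs[train_idx, , drop = FALSE]

    net <- init_network(spec)
    pre <- train_reconstruction(net, Xtr, config)
    net <- pre$net

    Ztr <- net_forward(net, Xtr, training = FALSE, upto = net$n_encoder)$out
    centers <- init_centers(Ztr, K)

    state <- adam_init(net)
    t <- 0L
    history <- data.frame(epoch = integer(0), clustering = numeric(0),
                          reconstruction = numeric(0), total = numeric(0))
    for (epoch in seq_len(config$joint_epochs)) {
      Ztr <- net_forward(net, Xtr, training = FALSE, upto = net$n_encoder)$out
      labels <- assign_clusters(Ztr, centers)

      if (config$learning_rate > 0) {
        ord <- sample.int(n_train)
        batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
        for (idx in batches) {
          Xb <- Xtr[idx, , drop = FALSE]
          fw <- net_forward(net, Xb, training = TRUE)
          net <- fw$net
          Zb <- fw$caches[[net$n_encoder]]$out
          dZ <- 2 * (Zb - centers[labels[idx], , drop = FALSE]) / length(idx)
          dOut <- NULL
          if (config$alpha > 0) {
            dOut <- config$alpha * 2 * (fw$out - Xb) / length(idx)
          }
          if (!all(is.finite(dZ)) || (!is.null(dOut) && !all(is.finite(dOut)))) {
            stop(sprintf("joint training diverged at epoch %d (learning rate %g)",
                         epoch, config$learning_rate), call. = FALSE)
          }
          grads <- net_backward(net, fw$caches, dOut, dZ_extra = dZ)
          t <- t + 1L
          upd <- adam_step(net, grads, state, t, config)
          net <- upd$net
          state <- upd$state
        }
        Ztr <- net_forward(net, Xtr, training = FALSE, upto = net$n_encoder)$out
        labels <- assign_clusters(Ztr, centers)
      }
      centers <- update_centers(Ztr, labels, K, centers)

      Xrec <- net_forward(net, Xtr, training = FALSE)$out
      lo <- dcae_loss(Xtr, Xrec, Ztr, centers, assign_clusters(Ztr, centers),
                      config$alpha)
      history <- rbind(history, data.frame(epoch = epoch,
                                           clustering = lo$clustering,
                                           reconstruction = lo$reconstruction,
                                           total = lo$total))
    }
  })

  ae <- structure(list(net = net, spec = spec, scaling = scaling,
                       history = pre$history, config = config),
                  class = "autoencoder")
  model <- structure(list(ae = ae, centers = centers, config = config,
                          spec = spec, pretrain_history = pre$history,
                          joint_history = history),
                     class = "dcae_model")

  Z_all <- encode(ae, X)
  labels_all <- assign_clusters(Z_all, centers)
  is_training <- seq_len(n) %in% train_idx
  result <- structure(list(labels = labels_all, embedding = Z_all,
                           is_training = is_training,
                           row_ids = row_ids %||% as.character(seq_len(n))),
                      class = "clustering_result")
  list(model = model, result = result)
}

# k-means with 20 random restarts on the pretrained embeddings; falls back
# to distinct-point seeding when duplicates would break stats::kmeans.
init_centers <- function(Z, K) {
  uz <- unique(Z)
  if (nrow(uz) <= K) {
    centers <- matrix(NA_real_, K, ncol(Z))
    centers[seq_len(nrow(uz)), ] <- uz
    if (K > nrow(uz)) {
      centers[(nrow(uz) + 1L):K, ] <- uz[sample.int(nrow(uz), K - nrow(uz),
                                                    replace = TRUE), , drop = FALSE]
    }
    return(centers)
  }
  km <- suppressWarnings(stats::kmeans(Z, centers = K, nstart = 20L,
                                       iter.max = 50L))
  km$centers
}

#' Assign new samples with a trained DCAE model
#'
#' Embeds `X_new` with the trained encoder (inference mode, stored min-max
#' scaling) and assigns each row to its nearest cluster center.
#'
#' @param model a `dcae_model` from [train_dcae()].
#' @param X_new matrix or `feature_matrix` with the training dimensionality.
#' @return integer labels in `1..K`.
#' @export
predict_clusters <- function(model, X_new) {
  stopifnot(inherits(model, "dcae_model"))
  assign_clusters(encode(model, X_new), model$centers)
}

#' @export
encode.dcae_model <- function(model, X) encode(model$ae, X)

#' @export
reconstruct.dcae_model <- function(model, X) reconstruct(model$ae, X)

#' @exportS3Method print dcae_model
print.dcae_model <- function(x, ...) {
  cat(sprintf("dcae_model: %d clusters, embedding dim %d, alpha = %g\n",
              nrow(x$centers), ncol(x$centers), x$config$alpha))
  invisible(x)
}

#' @exportS3Method print clustering_result
print.clustering_result <- function(x, ...) {
  cat(sprintf("clustering_result: %d samples in %d clusters\n",
              length(x$labels), length(unique(x$labels))))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Persist / load a DCAE model as plain text
#'
#' Writes each parameter array as a delimited text file plus a JSON metadata
#' file (architecture, config, histories) under `dir`.
#'
#' @param model a `dcae_model`.
#' @param dir output directory.
#' @return `dir` invisibly (`write`); the `dcae_model` (`read`).
#' @export
write_dcae_model <- function(model, dir) {
  stopifnot(inherits(model, "dcae_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arrays <- list(centers = model$centers,
                 scaling_mins = model$ae$scaling$mins,
                 scaling_range = model$ae$scaling$range)
  for (l in seq_along(model$ae$net$layers)) {
    layer <- model$ae$net$layers[[l]]
    for (p in intersect(c("W", "b", "gamma", "beta", "rmean", "rvar"),
                        names(layer))) {
      if (!is.null(layer[[p]])) arrays[[sprintf("layer%02d_%s", l, p)]] <- layer[[p]]
    }
  }
  for (nm in names(arrays)) {
    write.table(as.matrix(arrays[[nm]]), file.path(dir, paste0(nm, ".tsv")),
                sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  meta <- list(spec = unclass(model$spec), config = unclass(model$config),
               n_layers = length(model$ae$net$layers),
               n_encoder = model$ae$net$n_encoder,
               layer_bn = vapply(model$ae$net$layers, function(l) l$bn, logical(1)),
               pretrain_history = model$pretrain_history,
               joint_history = model$joint_history)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dcae_model
#' @export
read_dcae_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  spec <- do.call(network_spec, meta$spec[c("input_dim", "encoder_sizes",
                                            "use_batch_norm")])
  config <- do.call(training_config, meta$config[names(formals(training_config))])
  rd <- function(nm) as.matrix(read.delim(file.path(dir, paste0(nm, ".tsv")),
                                          header = FALSE))
  layers <- vector("list", meta$n_layers)
  for (l in seq_len(meta$n_layers)) {
    bn <- meta$layer_bn[l]
    layer <- list(W = unname(rd(sprintf("layer%02d_W", l))),
                  b = drop(rd(sprintf("layer%02d_b", l))),
                  bn = bn, act = "sigmoid")
    if (bn) {
      layer$gamma <- drop(rd(sprintf("layer%02d_gamma", l)))
      layer$beta <- drop(rd(sprintf("layer%02d_beta", l)))
      layer$rmean <- drop(rd(sprintf("layer%02d_rmean", l)))
      layer$rvar <- drop(rd(sprintf("layer%02d_rvar", l)))
    }
    layers[[l]] <- layer
  }
  net <- list(layers = layers, n_encoder = meta$n_encoder)
  scaling <- list(mins = drop(rd("scaling_mins")), range = drop(rd("scaling_range")))
  ae <- structure(list(net = net, spec = spec, scaling = scaling,
                       history = meta$pretrain_history, config = config),
                  class = "autoencoder")
  structure(list(ae = ae, centers = unname(rd("centers")), config = config,
                 spec = spec, pretrain_history = meta$pretrain_history,
                 joint_history = meta$joint_history),
            class = "dcae_model")
}
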