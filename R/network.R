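#' Network architecture specification
#'
#' The encoder is a stack of fully connected layers (defaults 1024, 512, 256
#' nodes) with batch normalization after each linear map and before the
#' sigmoid activation; the final encoder layer is the embedding (dimension
#' `v = ` last encoder size). The decoder mirrors the encoder
#' (256 -> 512 -> 1024 -> d) with the same batch-norm-then-sigmoid pattern on
#' its hidden layers; its output layer is plain sigmoid (no batch norm),
#' matched to inputs min-max scaled into \[0, 1\].
#'
#' @param input_dim number of input features d.
#' @param encoder_sizes integer vector of encoder layer widths.
#' @param use_batch_norm apply batch normalization on hidden layers.
#' @return object of class `network_spec`.
#' @export
network_spec <- function(input_dim, encoder_sizes = c(1024L, 512L, 256L),
                         use_batch_norm = TRUE) {
  encoder_sizes <- as.integer(encoder_sizes)
  if (input_dim < 1L || length(encoder_sizes) < 1L || any(encoder_sizes < 1L)) {
    stop("layer sizes must be positive", call. = FALSE)
  }
  structure(list(input_dim = as.integer(input_dim),
                 encoder_sizes = encoder_sizes,
                 use_batch_norm = isTRUE(use_batch_norm)),
            class = "network_spec")
}

#' Training configuration
#'
#' Defaults follow the experimental settings of the method: Adam with
#' beta1 = 0.9, beta2 = 0.999, learning rate 1e-4, mini-batch size 100,
#' L1-norm regularization weight 5e-3 on the connection weights, and a
#' random half/half train--evaluation split.
#'
#' @param alpha weight of the reconstruction term in the joint objective
#'   (alpha = 0 is the reconstruction-free "DC" ablation).
#' @param n_clusters number of clusters K.
#' @param learning_rate Adam step size (0 freezes the network: alternation
#'   reduces to Lloyd's algorithm on fixed embeddings).
#' @param adam_beta1,adam_beta2 Adam moment decay rates.
#' @param batch_size mini-batch size.
#' @param l1_lambda L1 regularization weight on connection weights.
#' @param pretrain_epochs,joint_epochs epoch budgets for the autoencoder
#'   pretraining stage and the joint clustering stage.
#' @param train_fraction fraction of patients used for gradient training;
#'   the remainder is embedded and assigned to the nearest final center.
#' @param scaling input min-max scaling mode: `"global"` (overall min/max,
#'   preserves relative column amplitudes; default) or `"column"`
#'   (per-feature).
#' @param seed integer seed governing all randomness (split, initialization,
#'   batch order).
#' @return object of class `training_config`.
#' @export
training_config <- function(alpha = 0.3, n_clusters = 4L,
                            learning_rate = 1e-4,
                            adam_beta1 = 0.9, adam_beta2 = 0.999,
                            batch_size = 100L, l1_lambda = 5e-3,
                            pretrain_epochs = 30L, joint_epochs = 15L,
                            train_fraction = 0.5, scaling = "global",
                            seed = 1L) {
  if (alpha < 0) stop("'alpha' must be non-negative", call. = FALSE)
  if (n_clusters < 1L) stop("'n_clusters' must be >= 1", call. = FALSE)
  if (train_fraction <= 0 || train_fraction > 1) {
    stop("'train_fraction' must be in (0, 1]", call. = FALSE)
  }
  structure(list(alpha = alpha, n_clusters = as.integer(n_clusters),
                 learning_rate = learning_rate, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, batch_size = as.integer(batch_size),
                 l1_lambda = l1_lambda,
                 pretrain_epochs = as.integer(pretrain_epochs),
                 joint_epochs = as.integer(joint_epochs),
                 train_fraction = train_fraction,
                 scaling = match.arg(scaling, c("global", "column")),
                 seed = as.integer(seed)),
            class = "training_config")
}

# ---- internal network machinery ------------------------------------------
# A network is a list of layers; each layer holds a weight matrix W
# (n_in x n_out), bias b, and, when batch-normalized, scale gamma, shift
# beta, and running mean/variance for inference mode. Activation is sigmoid
# on every layer except where act = "linear".

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

init_layer <- function(n_in, n_out, bn, act = "sigmoid") {
  lim <- sqrt(6 / (n_in + n_out))   # Glorot uniform
  list(W = matrix(runif(n_in * n_out, -lim, lim), n_in, n_out),
       b = numeric(n_out),
       bn = bn,
       gamma = if (bn) rep(1, n_out), beta = if (bn) numeric(n_out),
       rmean = if (bn) numeric(n_out), rvar = if (bn) rep(1, n_out),
       act = act)
}

init_network <- function(spec) {
  enc <- spec$encoder_sizes
  dims <- c(spec$input_dim, enc, rev(enc)[-1], spec$input_dim)
  n_layers <- length(dims) - 1L
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    is_output <- l == n_layers
    layers[[l]] <- init_layer(dims[l], dims[l + 1L],
                              bn = spec$use_batch_norm && !is_output,
                              act = "sigmoid")
  }
  list(layers = layers, n_encoder = length(enc))
}

layer_forward <- function(layer, A, training) {
  S <- A %*% layer$W
  S <- sweep(S, 2L, layer$b, "+")
  cache <- list(A_in = A, S = S)
  if (layer$bn) {
    if (training) {
      mu <- colMeans(S)
      v <- colMeans(S^2) - mu^2
      v[v < 0] <- 0
      layer$rmean <- BN_MOMENTUM * layer$rmean + (1 - BN_MOMENTUM) * mu
      layer$rvar <- BN_MOMENTUM * layer$rvar + (1 - BN_MOMENTUM) * v
    } else {
      mu <- layer$rmean
      v <- layer$rvar
    }
    istd <- 1 / sqrt(v + BN_EPS)
    Shat <- sweep(sweep(S, 2L, mu, "-"), 2L, istd, "*")
    Y <- sweep(sweep(Shat, 2L, layer$gamma, "*"), 2L, layer$beta, "+")
    cache$Shat <- Shat
    cache$istd <- istd
  } else {
    Y <- S
  }
  out <- if (layer$act == "sigmoid") 1 / (1 + exp(-Y)) else Y
  cache$out <- out
  list(layer = layer, out = out, cache = cache)
}

net_forward <- function(net, X, training = FALSE, upto = NULL) {
  upto <- upto %||% length(net$layers)
  caches <- vector("list", upto)
  A <- X
  for (l in seq_len(upto)) {
    fw <- layer_forward(net$layers[[l]], A, training)
    net$layers[[l]] <- fw$layer   # running BN stats updated in training mode
    caches[[l]] <- fw$cache
    A <- fw$out
  }
  list(net = net, out = A, caches = caches)
}

layer_backward <- function(layer, cache, dOut) {
  dY <- if (layer$act == "sigmoid") dOut * cache$out * (1 - cache$out) else dOut
  grads <- list()
  if (layer$bn) {
    B <- nrow(dY)
    grads$gamma <- colSums(dY * cache$Shat)
    grads$beta <- colSums(dY)
    dShat <- sweep(dY, 2L, layer$gamma, "*")
    s1 <- colSums(dShat)
    s2 <- colSums(dShat * cache$Shat)
    dS <- dShat * B
    dS <- sweep(dS, 2L, s1, "-")
    dS <- dS - sweep(cache$Shat, 2L, s2, "*")
    dS <- sweep(dS, 2L, cache$istd / B, "*")
  } else {
    dS <- dY
  }
  grads$W <- crossprod(cache$A_in, dS)
  grads$b <- colSums(dS)
  dA_in <- tcrossprod(dS, layer$W)
  list(grads = grads, dA_in = dA_in)
}

# Backpropagate through all layers; dOut is the gradient at the decoder
# output, dZ_extra an additional gradient injected at the embedding layer
# output (the clustering term). Either may be NULL.
net_backward <- function(net, caches, dOut, dZ_extra = NULL) {
  n_layers <- length(net$layers)
  grads <- vector("list", n_layers)
  dA <- dOut
  for (l in rev(seq_len(n_layers))) {
    if (l == net$n_encoder && !is.null(dZ_extra)) {
      dA <- if (is.null(dA)) dZ_extra else dA + dZ_extra
    }
    if (is.null(dA)) {
      # no gradient flows above this point (decoder layers under a pure
      # clustering objective); leave the slot NULL
      next
    }
    bw <- layer_backward(net$layers[[l]], caches[[l]], dA)
    grads[l] <- list(bw$grads)
    dA <- bw$dA_in
  }
  grads
}

adam_init <- function(net) {
  lapply(net$layers, function(layer) {
    st <- list(W = list(m = layer$W * 0, v = layer$W * 0),
               b = list(m = layer$b * 0, v = layer$b * 0))
    if (layer$bn) {
      st$gamma <- list(m = layer$gamma * 0, v = layer$gamma * 0)
      st$beta <- list(m = layer$beta * 0, v = layer$beta * 0)
    }
    st
  })
}

adam_step <- function(net, grads, state, t, config) {
  b1 <- config$adam_beta1; b2 <- config$adam_beta2
  lr <- config$learning_rate; eps <- 1e-8
  for (l in seq_along(net$layers)) {
    g <- grads[[l]]
    if (is.null(g)) next
    # L1 subgradient on connection weights only
    if (config$l1_lambda > 0) g$W <- g$W + config$l1_lambda * sign(net$layers[[l]]$W)
    for (p in names(g)) {
      st <- state[[l]][[p]]
      st$m <- b1 * st$m + (1 - b1) * g[[p]]
      st$v <- b2 * st$v + (1 - b2) * g[[p]]^2
      mhat <- st$m / (1 - b1^t)
      vhat <- st$v / (1 - b2^t)
      net$layers[[l]][[p]] <- net$layers[[l]][[p]] - lr * mhat / (sqrt(vhat) + eps)
      state[[l]][[p]] <- st
    }
  }
  list(net = net, state = state)
}

# Min-max scale into [0, 1] for the sigmoid decoder. "global" (default)
# scales by the overall min/max so the relative amplitudes of columns are
# preserved; "column" rescales each feature independently, which equalizes
# rare low-count noise codes with high-signal codes and is kept only as an
# option.
fit_scaling <- function(X, method = c("global", "column")) {
  method <- match.arg(method)
  if (method == "global") {
    gmin <- min(X)
    rng <- max(X) - gmin
    if (rng == 0) rng <- 1
    return(list(mins = rep(gmin, ncol(X)), range = rep(rng, ncol(X))))
  }
  mins <- apply(X, 2L, min)
  maxs <- apply(X, 2L, max)
  rng <- maxs - mins
  rng[rng == 0] <- 1
  list(mins = mins, range = rng)
}

apply_scaling <- function(X, scaling) {
  sweep(sweep(X, 2L, scaling$mins, "-"), 2L, scaling$range, "/")
}

l1_penalty <- function(net, lambda) {
  if (lambda <= 0) return(0)
  lambda * sum(vapply(net$layers, function(l) sum(abs(l$W)), numeric(1)))
}

#' Mean squared reconstruction error
#'
#' The autoencoder objective: `(1/N) * sum_i ||x'_i - x_i||^2`, the squared
#' L2 reconstruction error averaged over samples.
#'
#' @param X input matrix (N x d).
#' @param X_prime reconstruction matrix of identical shape.
#' @return non-negative scalar.
#' @examples
#' reconstruction_loss(matrix(0, 1, 2), matrix(c(3, 4), 1))  # 25
#' @export
reconstruction_loss <- function(X, X_prime) {
  X <- as_matrix_input(X); X_prime <- as_matrix_input(X_prime)
  if (!identical(dim(X), dim(X_prime))) {
    stop("'X' and 'X_prime' must have identical dimensions", call. = FALSE)
  }
  sum((X_prime - X)^2) / nrow(X)
}

#' Pretrain the deep autoencoder
#'
#' Minimizes mean squared reconstruction error plus an L1 penalty on the
#' connection weights by mini-batch Adam. Inputs are min-max scaled per
#' feature column into \[0, 1\] so the sigmoid decoder output can represent
#' them; the fitted scaling is stored with the model and reapplied by
#' [encode()] and [reconstruct()].
#'
#' @param X numeric matrix or `feature_matrix` (patients x features).
#' @param spec a [network_spec()]; defaults to the standard architecture for
#'   `ncol(X)` inputs.
#' @param config a [training_config()].
#' @return object of class `autoencoder` with elements `net`, `spec`,
#'   `scaling`, and `history` (per-epoch mean reconstruction loss on the
#'   training data, L1 penalty excluded).
#' @export
pretrain_autoencoder <- function(X, spec = NULL, config = training_config()) {
  X <- as_matrix_input(X)
  spec <- spec %||% network_spec(ncol(X))
  if (spec$input_dim != ncol(X)) stop("spec input_dim does not match ncol(X)", call. = FALSE)
  withr::with_seed(config$seed, {
    scaling <- fit_scaling(X, config$scaling %||% "global")
    Xs <- apply_scaling(X, scaling)
    net <- init_network(spec)
    fit <- train_reconstruction(net, Xs, config)
  })
  structure(list(net = fit$net, spec = spec, scaling = scaling,
                 history = fit$history, config = config),
            class = "autoencoder")
}

train_reconstruction <- function(net, Xs, config) {
  n <- nrow(Xs)
  state <- adam_init(net)
  t <- 0L
  history <- numeric(config$pretrain_epochs)
  for (epoch in seq_len(config$pretrain_epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    epoch_loss <- 0
    for (idx in batches) {
      Xb <- Xs[idx, , drop = FALSE]
      fw <- net_forward(net, Xb, training = TRUE)
      net <- fw$net
      resid <- fw$out - Xb
      loss <- sum(resid^2) / length(idx)
      if (!is.finite(loss)) {
        stop(sprintf("autoencoder training diverged at epoch %d (learning rate %g)",
                     epoch, config$learning_rate), call. = FALSE)
      }
      epoch_loss <- epoch_loss + loss * length(idx)
      if (config$learning_rate > 0) {
        dOut <- 2 * resid / length(idx)
        grads <- net_backward(net, fw$caches, dOut)
        t <- t + 1L
        upd <- adam_step(net, grads, state, t, config)
        net <- upd$net
        state <- upd$state
      }
    }
    history[epoch] <- epoch_loss / n
  }
  list(net = net, history = history)
}

#' Embed samples with a trained encoder
#'
#' @param model an `autoencoder` or `dcae_model`.
#' @param X matrix or `feature_matrix` with the training dimensionality.
#' @return N x v embedding matrix (v = last encoder layer size). Inference
#'   mode: batch-norm layers use their running statistics.
#' @export
encode <- function(model, X) {
  UseMethod("encode")
}

#' @export
encode.autoencoder <- function(model, X) {
  X <- as_matrix_input(X)
  if (ncol(X) != model$spec$input_dim) {
    stop(sprintf("X has %d columns; model expects %d", ncol(X),
                 model$spec$input_dim), call. = FALSE)
  }
  Xs <- apply_scaling(X, model$scaling)
  net_forward(model$net, Xs, training = FALSE, upto = model$net$n_encoder)$out
}

#' Reconstruct samples through the full autoencoder
#'
#' @inheritParams encode
#' @return N x d reconstruction on the min-max scale (in \[0, 1\]).
#' @export
reconstruct <- function(model, X) {
  UseMethod("reconstruct")
}

#' @export
reconstruct.autoencoder <- function(model, X) {
  X <- as_matrix_input(X)
  Xs <- apply_scaling(X, model$scaling)
  net_forward(model$net, Xs, training = FALSE)$out
}

#' @exportS3Method print autoencoder
print.autoencoder <- function(x, ...) {
  cat(sprintf("autoencoder: %d -> %s (embedding dim %d)\n",
              x$spec$input_dim,
              paste(x$spec$encoder_sizes, collapse = " -> "),
              rev(x$spec$encoder_sizes)[1]))
  invisible(x)
}
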