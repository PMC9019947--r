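#' Read an experiment configuration file
#'
#' YAML with any of: `events` / `category_map` / `labels` (input paths),
#' `output_dir`, `method` (one of `kmeans_pca`, `hc`, `consensus`,
#' `dae_kmeans`, `dc`, `dcae`, or `all`), `k_list` (default
#' 2, 5, 9, 13, 17, 21), `seed`, `pca_dim`, `hc_linkage`, `consensus`
#' (`H`, `subsample_fraction`), `network` ([network_spec()] fields) and
#' `training` ([training_config()] fields).
#'
#' @param path YAML file path.
#' @return a named list (class `experiment_config`) with defaults filled in.
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_experiment_config(cfg)
}

#' @rdname read_experiment_config
#' @param cfg a named list of settings.
#' @export
as_experiment_config <- function(cfg = list()) {
  defaults <- list(method = "dcae", k_list = c(2L, 5L, 9L, 13L, 17L, 21L),
                   seed = 1L, pca_dim = 256L, hc_linkage = "ward",
                   consensus = list(H = 50L, subsample_fraction = 0.8),
                   network = list(), training = list())
  out <- utils::modifyList(defaults, cfg)
  if (any(out$k_list < 1L)) stop("k_list values must be >= 1", call. = FALSE)
  structure(out, class = "experiment_config")
}

experiment_methods <- c("kmeans_pca", "hc", "consensus", "dae_kmeans", "dc",
                        "dcae")

build_training_config <- function(config, K, seed) {
  args <- config$training
  args$n_clusters <- K
  args$seed <- seed
  do.call(training_config, args[names(args) %in% names(formals(training_config))])
}

build_network_spec <- function(config, d) {
  args <- config$network
  args$input_dim <- d
  do.call(network_spec, args[names(args) %in% names(formals(network_spec))])
}

# Run one clustering method at one K; returns labels and the representation
# silhouette should be computed in (each method's own space).
run_method <- function(method, fm, config, K, seed) {
  X <- as_matrix_input(fm)
  pca_dim <- min(config$pca_dim, ncol(X), nrow(X) - 1L)
  switch(
    method,
    kmeans_pca = {
      fit <- kmeans_pca(X, K, pca_dim, seed = seed)
      list(labels = fit$labels, space = fit$reduced)
    },
    hc = {
      red <- pca_project(X, pca_dim)$scores
      fit <- hierarchical_clustering(red, K, config$hc_linkage)
      list(labels = fit$labels, space = red)
    },
    consensus = {
      red <- pca_project(X, pca_dim)$scores
      fit <- consensus_clustering(red, K, H = config$consensus$H,
                                  subsample_fraction =
                                    config$consensus$subsample_fraction,
                                  seed = seed)
      list(labels = fit$labels, space = red)
    },
    dae_kmeans = {
      fit <- dae_kmeans(X, build_network_spec(config, ncol(X)),
                        build_training_config(config, K, seed))
      list(labels = fit$labels, space = fit$embedding)
    },
    dc = {
      fit <- dc_clustering(X, build_network_spec(config, ncol(X)),
                           build_training_config(config, K, seed))
      list(labels = fit$result$labels, space = fit$result$embedding,
           model = fit$model)
    },
    dcae = {
      fit <- train_dcae(X, build_network_spec(config, ncol(X)),
                        build_training_config(config, K, seed))
      list(labels = fit$result$labels, space = fit$result$embedding,
           model = fit$model)
    },
    stop("unknown method: ", method, call. = FALSE))
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(unclass(config)), f)
  unname(tools::md5sum(f))
}

#' Run a full clustering experiment
#'
#' Featurizes the event table, runs the configured method(s) for every K in
#' `k_list`, computes purity (when class labels are available), silhouette
#' and the CC-dominated cluster count, and writes assignment tables, a
#' metrics table, and a JSON metadata record (seed, config hash) under
#' `output_dir`. Reruns with the same configuration are reproducible; input
#' files are never modified.
#'
#' @param config an `experiment_config` (or list coerced through
#'   [as_experiment_config()]). `events` may be a path or a data.frame;
#'   `labels` (optional) a path or data.frame with `patient_id` and `class`.
#' @param output_dir overrides `config$output_dir`.
#' @return the metrics data.frame (method, K, alpha, purity, silhouette,
#'   nccd, seed), invisibly; written as `metrics.tsv`.
#' @export
run_experiment <- function(config, output_dir = NULL) {
  config <- as_experiment_config(unclass(config))
  output_dir <- output_dir %||% config$output_dir %||%
    stop("no output_dir configured", call. = FALSE)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  events <- config$events
  if (is.character(events)) events <- read_event_table(events)
  if (is.null(events)) stop("stage featurize: no events supplied", call. = FALSE)
  fm <- build_feature_matrix(events)
  write_feature_matrix(fm, file.path(output_dir, "features"))

  classes <- NULL
  if (!is.null(config$labels)) {
    lab <- config$labels
    if (is.character(lab)) lab <- read.csv(lab, stringsAsFactors = FALSE)
    classes <- lab$class[match(fm$row_ids, lab$patient_id)]
  }

  methods <- if (identical(config$method, "all")) experiment_methods else config$method
  metrics <- list()
  for (method in methods) {
    for (K in config$k_list) {
      fit <- tryCatch(
        run_method(method, fm, config, K, config$seed),
        error = function(e) stop(sprintf("stage %s (K = %d): %s", method, K,
                                         conditionMessage(e)), call. = FALSE))
      assign_tab <- data.frame(patient_id = fm$row_ids,
                               cluster_label = fit$labels,
                               is_training_row = NA)
      write.table(assign_tab,
                  file.path(output_dir,
                            sprintf("assignments_%s_K%d.tsv", method, K)),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      sil <- if (K > 1L) silhouette_score(fit$space, fit$labels) else NA_real_
      alpha <- if (method == "dcae") {
        build_training_config(config, K, config$seed)$alpha
      } else if (method == "dc") 0 else NA_real_
      metrics[[length(metrics) + 1L]] <- data.frame(
        method = method, K = K, alpha = alpha,
        purity = if (is.null(classes)) NA_real_ else purity(fit$labels, classes),
        silhouette = sil,
        nccd = if (is.null(classes)) NA_integer_ else
          count_dominated_clusters(fit$labels, classes),
        seed = config$seed)
    }
  }
  metrics <- do.call(rbind, metrics)
  write.table(metrics, file.path(output_dir, "metrics.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)

  jsonlite::write_json(
    list(seed = config$seed, config_hash = config_hash(config),
         methods = methods, k_list = config$k_list,
         n_patients = nrow(fm$values), n_codes = ncol(fm$values),
         package_version = as.character(utils::packageVersion("coughclust"))),
    file.path(output_dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(metrics)
}

#' Compare all clustering methods across K
#'
#' Convenience wrapper around [run_experiment()] with `method = "all"`:
#' one row per (method, K) with purity, silhouette and the CC-dominated
#' cluster count.
#'
#' @inheritParams run_experiment
#' @return long metrics data.frame.
#' @export
compare_methods <- function(config, output_dir = NULL) {
  config <- as_experiment_config(unclass(config))
  config$method <- "all"
  run_experiment(config, output_dir)
}
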