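#' Assemble a full-pipeline configuration
#'
#' @param layer_paths character paths to layer TSV files (see
#'   [read_omics_tsv()]).
#' @param out_dir output directory (created if absent).
#' @param max_missing_rate,impute_k,n_keep preprocessing switches; `n_keep`
#'   may be a vector (one entry per layer) or `NULL` to keep all features.
#' @param K,mu affinity parameters.
#' @param method `"hopes"` or `"snf"`.
#' @param alpha,beta,rho,tol,max_iter fusion solver parameters.
#' @param k cluster count; `NULL` uses the eigengap estimate.
#' @param consensus run Monti-style consensus clustering.
#' @param reps,fraction consensus parameters.
#' @param truth_path,survival_path,categories_path optional label TSV,
#'   survival TSV and categorical-label TSV for evaluation.
#' @param n_top_features per-layer feature-ranking size (0 disables).
#' @param intersect allow intersecting sample sets across layers instead of
#'   requiring identical ordering.
#' @param seed RNG seed governing all stochastic steps.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(layer_paths, out_dir,
                            max_missing_rate = 0.2, impute_k = 10,
                            n_keep = NULL,
                            K = NULL, mu = 0.5,
                            method = c("hopes", "snf"),
                            alpha = 1, beta = 1, rho = 1, tol = 1e-6,
                            max_iter = 500,
                            k = NULL, consensus = FALSE, reps = 100,
                            fraction = 0.8,
                            truth_path = NULL, survival_path = NULL,
                            categories_path = NULL,
                            n_top_features = 15, intersect = FALSE,
                            seed = 1) {
  method <- match.arg(method)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Any field of [pipeline_config()] may appear in the YAML file; unknown
#' fields are rejected.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stopf("reading YAML configs requires the 'yaml' package")
  cfg <- yaml::read_yaml(path)
  allowed <- names(formals(pipeline_config))
  bad <- setdiff(names(cfg), allowed)
  if (length(bad))
    stopf("unknown config field(s): %s", paste(bad, collapse = ", "))
  if (is.null(cfg$layer_paths)) stopf("config must list layer_paths")
  if (is.null(cfg$out_dir)) stopf("config must give out_dir")
  do.call(pipeline_config, cfg)
}

align_layers <- function(layers, intersect = FALSE) {
  ref <- sample_ids(layers[[1L]])
  if (intersect) {
    for (l in layers[-1L]) ref <- base::intersect(ref, sample_ids(l))
    if (length(ref) < 2L) stopf("fewer than 2 samples shared across layers")
    layers <- lapply(layers, function(l)
      omics_layer(l$values[match(ref, sample_ids(l)), , drop = FALSE],
                  layer_name = l$layer_name))
  } else {
    for (l in layers[-1L]) {
      ids <- sample_ids(l)
      bad <- union(setdiff(ids, ref), setdiff(ref, ids))
      if (length(bad) > 0L || !identical(ids, ref))
        stopf("layer '%s': sample ids do not match the first layer%s%s",
              l$layer_name,
              if (length(bad)) "; offending ids: " else " (ordering differs)",
              paste(utils::head(bad, 10L), collapse = ", "))
    }
  }
  layers
}

#' Run the full integration pipeline
#'
#' preprocess -> per-layer affinities -> fuse -> cluster -> evaluate ->
#' feature selection, writing every artifact (fused matrix, labels, metrics
#' JSON, per-layer feature rankings) plus a manifest to `cfg$out_dir`.
#' Deterministic under identical config and seed.
#'
#' @param cfg a [pipeline_config()].
#' @return The manifest (named list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  msg <- function(...) message("[hopes] ", sprintf(...))

  for (p in cfg$layer_paths)
    if (!file.exists(p)) stopf("layer file not found: %s", p)
  if (!is.null(cfg$survival_path) && !file.exists(cfg$survival_path))
    stopf("survival file not found: %s", cfg$survival_path)
  if (!is.null(cfg$truth_path) && !file.exists(cfg$truth_path))
    stopf("truth label file not found: %s", cfg$truth_path)

  msg("reading %d layers", length(cfg$layer_paths))
  layers <- lapply(cfg$layer_paths, read_omics_tsv)
  layers <- align_layers(layers, cfg$intersect)

  n_keep <- cfg$n_keep
  if (!is.null(n_keep) && length(n_keep) == 1L)
    n_keep <- rep(n_keep, length(layers))
  msg("preprocessing")
  raw_layers <- layers
  layers <- lapply(seq_along(layers), function(i)
    preprocess_layer(layers[[i]], cfg$max_missing_rate, cfg$impute_k,
                     if (is.null(n_keep)) NULL else n_keep[i]))
  dataset <- multi_omics(layers)

  msg("building affinities (K = %s, mu = %.2f)",
      cfg$K %||% "auto", cfg$mu)
  aff <- build_affinities(dataset, K = cfg$K, mu = cfg$mu)

  msg("fusing (%s)", cfg$method)
  fused <- if (cfg$method == "hopes") {
    hopes_fuse(aff$S_list, aff$mask_list,
               fusion_config(alpha = cfg$alpha, beta = cfg$beta,
                             rho = cfg$rho, tol = cfg$tol,
                             max_iter = cfg$max_iter, seed = cfg$seed))
  } else {
    snf_fuse(aff$P_list, aff$S_list)
  }
  w_path <- file.path(cfg$out_dir, "fused_similarity.tsv")
  write_similarity_tsv(fused, w_path)

  k <- cfg$k
  if (is.null(k)) {
    eg <- eigengap_estimate(fused, k_max = min(10L, nrow(fused$matrix) - 1L))
    k <- eg$k
    msg("eigengap estimate: k = %d (%s)", k,
        if (eg$confident) "confident" else "low confidence")
  }
  msg("clustering at k = %d%s", k, if (cfg$consensus) " (consensus)" else "")
  if (cfg$consensus) {
    cc <- consensus_cluster(fused, k, reps = cfg$reps,
                            subsample_fraction = cfg$fraction,
                            seed = cfg$seed)
    assignment <- cc$assignment
    write_similarity_tsv(cc$consensus,
                         file.path(cfg$out_dir, "consensus_matrix.tsv"))
  } else {
    assignment <- spectral_cluster(fused, k, seed = cfg$seed)
  }
  labels_path <- file.path(cfg$out_dir, "labels.tsv")
  write_labels_tsv(assignment, labels_path)

  metrics <- list(k = k, method = cfg$method,
                  converged = fused$converged)
  if (!is.null(cfg$truth_path)) {
    truth <- read_labels_tsv(cfg$truth_path)
    metrics$nmi <- nmi(assignment, truth)
    metrics$matched_accuracy <- matched_accuracy(assignment, truth)
  }
  if (!is.null(cfg$survival_path)) {
    surv <- read_survival_tsv(cfg$survival_path)
    lr <- logrank_test(assignment, surv)
    metrics$logrank_statistic <- lr$statistic
    metrics$logrank_p <- lr$p_value
  }
  if (!is.null(cfg$categories_path)) {
    cats <- utils::read.delim(cfg$categories_path, stringsAsFactors = FALSE)
    cat_labels <- cats[[2L]][match(assignment$sample_ids, cats[[1L]])]
    cs <- chi_square_association(assignment$labels, cat_labels)
    metrics$chisq_statistic <- cs$statistic
    metrics$chisq_p <- cs$p_value
  }
  metrics_path <- file.path(cfg$out_dir, "metrics.json")
  jsonlite::write_json(metrics, metrics_path, auto_unbox = TRUE, digits = NA)

  feature_paths <- character(0)
  if (cfg$n_top_features > 0) {
    msg("ranking features per layer (MCFS)")
    for (i in seq_along(raw_layers)) {
      lay <- layers[[i]]
      rk <- mcfs_scores(fused, lay, k_clusters = k)
      top <- select_top_features(rk, cfg$n_top_features)
      fp <- file.path(cfg$out_dir,
                      sprintf("features_%s.tsv", lay$layer_name))
      utils::write.table(
        data.frame(feature_id = rk$feature_ids, score = rk$scores,
                   selected = rk$feature_ids %in% top),
        fp, sep = "\t", quote = FALSE, row.names = FALSE)
      feature_paths <- c(feature_paths, fp)
    }
  }

  cfg_path <- file.path(cfg$out_dir, "config.json")
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))], cfg_path,
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  outputs <- c(w_path, labels_path, metrics_path, feature_paths, cfg_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("hopes")),
    r_version = R.version.string,
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                      basename(outputs))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  msg("done; outputs in %s", cfg$out_dir)
  invisible(manifest)
}
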