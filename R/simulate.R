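#' Per-layer specification for the synthetic generator
#'
#' @param n_features number of features the layer carries.
#' @param merge_map list of integer vectors; each vector names true clusters
#'   that share a mean in this layer and are therefore indistinguishable
#'   ("indivisible") from this layer alone.
#' @param signal_strength standard deviation of cluster-mean entries, in
#'   units of the noise sd at `noise_sd = 1`; controls mean separation.
#' @param name layer label.
#' @param n_components number of singular components used when seeding the
#'   layer from a real matrix (see [svd_seed_layers()]); `NULL` picks
#'   `min(10, rank)`.
#' @return A list of class `layer_spec`.
#' @export
layer_spec <- function(n_features, merge_map = list(), signal_strength = 1.5,
                       name = NULL, n_components = NULL) {
  stopifnot(n_features >= 1, signal_strength > 0)
  structure(list(n_features = as.integer(n_features), merge_map = merge_map,
                 signal_strength = signal_strength, name = name,
                 n_components = n_components),
            class = "layer_spec")
}

default_layer_specs <- function() list(
  layer_spec(500, list(c(1L, 2L)), name = "rna"),
  layer_spec(500, list(c(2L, 3L)), name = "methylation"),
  layer_spec(200, list(c(3L, 4L)), name = "mirna")
)

#' Configuration of the synthetic multi-omics benchmark
#'
#' The default emulates a clear-boundary benchmark: 200 samples in 4 equal
#' clusters observed through 3 layers (500/500/200 features, echoing the
#' usual expression/methylation/miRNA dimension asymmetry), where each layer
#' merges a different cluster pair so that no single layer can resolve all
#' four groups, under additive Gaussian noise. Setting `fuzzy_fraction > 0`
#' produces the fuzzy-boundary variant, in which a fraction of "edge"
#' samples is interpolated toward a neighbouring cluster's mean.
#'
#' @param n_samples cohort size.
#' @param n_clusters number of true clusters (default 4).
#' @param cluster_proportions cluster size fractions summing to 1
#'   (default: equal).
#' @param layer_specs list of [layer_spec()] objects.
#' @param noise_sd sd of the additive Gaussian noise.
#' @param fuzzy_fraction fraction of edge samples in `[0, 1)`; 0 gives clear
#'   boundaries.
#' @param fuzzy_mix interpolation weight of an edge sample toward the
#'   neighbouring cluster's mean (default 0.4).
#' @param seed RNG seed; identical config + seed gives bit-identical data.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 200, n_clusters = 4,
                       cluster_proportions = NULL, layer_specs = NULL,
                       noise_sd = 1, fuzzy_fraction = 0, fuzzy_mix = 0.4,
                       seed = 1) {
  layer_specs <- layer_specs %||% default_layer_specs()
  cluster_proportions <- cluster_proportions %||%
    rep(1 / n_clusters, n_clusters)
  stopifnot(n_samples >= n_clusters, n_clusters >= 2,
            length(cluster_proportions) == n_clusters,
            noise_sd >= 0, fuzzy_fraction >= 0, fuzzy_fraction < 1,
            fuzzy_mix >= 0, fuzzy_mix <= 1)
  if (abs(sum(cluster_proportions) - 1) > 1e-8)
    stopf("cluster proportions must sum to 1")
  for (spec in layer_specs) {
    stopifnot(inherits(spec, "layer_spec"))
    for (grp in spec$merge_map)
      if (any(grp < 1 | grp > n_clusters))
        stopf("merge_map references cluster outside 1..%d", n_clusters)
  }
  # every true cluster pair should be separable in at least one layer
  effs <- lapply(layer_specs, function(s)
    effective_clusters(n_clusters, s$merge_map))
  for (a in seq_len(n_clusters - 1L)) for (b in (a + 1L):n_clusters) {
    sep <- any(vapply(effs, function(e) e[a] != e[b], logical(1)))
    if (!sep)
      warnf("clusters %d and %d are merged in every layer; they cannot be recovered",
            a, b)
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_clusters = as.integer(n_clusters),
                 cluster_proportions = cluster_proportions,
                 layer_specs = layer_specs, noise_sd = noise_sd,
                 fuzzy_fraction = fuzzy_fraction, fuzzy_mix = fuzzy_mix,
                 seed = seed),
            class = "sim_config")
}

# map true cluster ids to the layer's effective (merged) cluster ids 1..k_eff
effective_clusters <- function(k, merge_map) {
  eff <- seq_len(k)
  for (grp in merge_map) eff[eff %in% grp] <- min(grp)
  as.integer(factor(eff, levels = unique(eff)))
}

# deterministic cluster sizes from proportions (largest-remainder rounding
# via cumulative sums; sizes differ from exact proportions by at most 1)
cluster_sizes <- function(n, proportions) {
  bounds <- round(cumsum(proportions) * n)
  diff(c(0L, bounds))
}

# shared generator core; `projections` (one per layer: list(loadings,
# scales)) maps r-dimensional cluster scores into feature space. The RNG
# stream is: global edge-sample draws, then per layer means -> noise, so a
# projection with identity loadings reproduces the unprojected data exactly.
simulate_core <- function(cfg, projections = NULL) {
  k <- cfg$n_clusters
  n <- cfg$n_samples
  with_seed(cfg$seed, {
    sizes <- cluster_sizes(n, cfg$cluster_proportions)
    labels <- rep(seq_len(k), sizes)
    ids <- sprintf("S%03d", seq_len(n))

    n_fuzzy <- round(cfg$fuzzy_fraction * n)
    fuzzy_idx <- if (n_fuzzy > 0) sample.int(n, n_fuzzy) else integer(0)
    fuzzy_target <- vapply(fuzzy_idx, function(s) {
      others <- setdiff(seq_len(k), labels[s])
      others[sample.int(length(others), 1L)]
    }, integer(1))

    layers <- vector("list", length(cfg$layer_specs))
    for (l in seq_along(cfg$layer_specs)) {
      spec <- cfg$layer_specs[[l]]
      proj <- if (is.null(projections)) NULL else projections[[l]]
      dims <- if (is.null(proj)) spec$n_features else length(proj$scales)
      eff <- effective_clusters(k, spec$merge_map)
      n_eff <- max(eff)
      means <- matrix(stats::rnorm(n_eff * dims, sd = spec$signal_strength),
                      n_eff, dims)
      scores <- means[eff[labels], , drop = FALSE]
      for (f in seq_along(fuzzy_idx)) {
        s <- fuzzy_idx[f]
        tgt <- eff[fuzzy_target[f]]
        if (tgt != eff[labels[s]])
          scores[s, ] <- (1 - cfg$fuzzy_mix) * scores[s, ] +
            cfg$fuzzy_mix * means[tgt, ]
      }
      values <- if (is.null(proj)) scores
        else scores %*% (t(proj$loadings) * proj$scales)
      p_out <- ncol(values)
      values <- values +
        matrix(stats::rnorm(n * p_out, sd = cfg$noise_sd), n, p_out)
      fid <- if (is.null(proj) || is.null(proj$feature_ids))
        sprintf("%s_f%04d", spec$name %||% paste0("layer", l), seq_len(p_out))
        else proj$feature_ids
      layers[[l]] <- omics_layer(values, sample_ids = ids, feature_ids = fid,
                                 layer_name = spec$name %||% paste0("layer", l))
    }
    structure(list(dataset = multi_omics(layers),
                   true_labels = cluster_assignment(ids, labels, k),
                   config = cfg),
              class = "simulated_dataset")
  })
}

#' Generate a synthetic multi-omics dataset with planted clusters
#'
#' Each layer assigns every sample the mean vector of its effective cluster
#' (true clusters collapsed by the layer's `merge_map`), interpolates edge
#' samples toward a neighbouring cluster's mean, and adds i.i.d. Gaussian
#' noise. Deterministic under the config seed.
#'
#' @param cfg a [sim_config()].
#' @return A `simulated_dataset`: list with `dataset` (a [multi_omics()]),
#'   `true_labels` (a [cluster_assignment()]), and the echoed `config`.
#' @export
simulate_multiomics <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  simulate_core(cfg, projections = NULL)
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("<simulated_dataset> %d samples, %d clusters, %d layers, noise sd %.2g\n",
              x$config$n_samples, x$config$n_clusters,
              length(x$config$layer_specs), x$config$noise_sd))
  invisible(x)
}

#' Seed the generator's feature geometry from real omics matrices
#'
#' Takes the top right-singular vectors and singular-value spectrum of each
#' supplied real matrix as feature loadings and scales, generates cluster
#' scores in the component space from the planted-cluster model, and maps
#' them into feature space (`scores %*% diag(scales) %*% t(loadings)`)
#' before adding noise. The generated layer inherits the real layer's
#' feature count and leading feature-correlation geometry.
#'
#' @param real_matrices list of [omics_layer()]s or numeric matrices, one
#'   per entry in `cfg$layer_specs`.
#' @param cfg a [sim_config()]; each layer spec's `n_components` sets how
#'   many singular components are used (default `min(10, rank)`).
#' @return A `simulated_dataset`, as in [simulate_multiomics()].
#' @export
svd_seed_layers <- function(real_matrices, cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(real_matrices) != length(cfg$layer_specs))
    stopf("need one real matrix per layer spec (%d vs %d)",
          length(real_matrices), length(cfg$layer_specs))
  projections <- vector("list", length(real_matrices))
  for (l in seq_along(real_matrices)) {
    R <- real_matrices[[l]]
    if (inherits(R, "omics_layer")) R <- R$values
    R <- as.matrix(R)
    r <- cfg$layer_specs[[l]]$n_components %||% min(10L, min(dim(R)))
    sv <- svd(R, nu = 0, nv = r)
    rank <- sum(sv$d > max(dim(R)) * .Machine$double.eps * sv$d[1L])
    if (rank < r)
      stopf("layer %d: real matrix rank %d < requested %d components",
            l, rank, r)
    projections[[l]] <- list(
      loadings = sv$v[, seq_len(r), drop = FALSE],
      scales = sv$d[seq_len(r)] / sqrt(max(1, nrow(R) - 1)),
      feature_ids = colnames(R))
  }
  simulate_core(cfg, projections)
}

#' Noise-robustness sweep over fusion methods
#'
#' For every noise level and trial, regenerates the synthetic dataset,
#' builds per-layer affinities, runs each requested method, spectrally
#' clusters at the true k and records the NMI against the planted labels.
#'
#' @param cfg a [sim_config()]; its `noise_sd` is overridden by `sigmas`.
#' @param sigmas noise standard deviations to sweep.
#' @param trials repeated trials per noise level (default 20).
#' @param methods character vector drawn from `"hopes"`, `"snf"`, and
#'   `"layer<i>"` (cluster layer i's kernel affinity alone).
#' @param k number of clusters used downstream (default: true cluster
#'   count).
#' @param K,mu affinity parameters, see [affinity_config()].
#' @param fusion a [fusion_config()] used for the `"hopes"` runs.
#' @param snf_iterations iterations for the `"snf"` runs.
#' @return Tidy data frame with columns `method`, `sigma`, `trial`, `nmi`
#'   (one row per method x sigma x trial).
#' @export
noise_sweep <- function(cfg = sim_config(), sigmas = c(1, 2, 3), trials = 20,
                        methods = c("hopes", "snf"), k = cfg$n_clusters,
                        K = NULL, mu = 0.5, fusion = fusion_config(),
                        snf_iterations = 20) {
  stopifnot(trials >= 1, length(sigmas) >= 1, length(methods) >= 1)
  layer_idx <- function(m) as.integer(sub("^layer", "", m))
  for (m in methods)
    if (!m %in% c("hopes", "snf") &&
        !(grepl("^layer[0-9]+$", m) &&
          layer_idx(m) <= length(cfg$layer_specs)))
      stopf("unknown method '%s'", m)
  seeds <- matrix(derive_seeds(cfg$seed, length(sigmas) * trials),
                  length(sigmas), trials)
  out <- vector("list", length(sigmas) * trials)
  row <- 0L
  for (si in seq_along(sigmas)) {
    for (t in seq_len(trials)) {
      cfg_t <- cfg
      cfg_t$noise_sd <- sigmas[si]
      cfg_t$seed <- seeds[si, t]
      sim <- simulate_multiomics(cfg_t)
      norm_layers <- lapply(sim$dataset$layers, zscore_normalize)
      aff <- build_affinities(multi_omics(norm_layers), K = K, mu = mu)
      nmis <- vapply(methods, function(m) {
        Wm <- if (m == "hopes") {
          hopes_fuse(aff$S_list, aff$mask_list, fusion, trace = FALSE)
        } else if (m == "snf") {
          snf_fuse(aff$P_list, aff$S_list, iterations = snf_iterations)
        } else {
          aff$P_list[[layer_idx(m)]]
        }
        cl <- spectral_cluster(Wm, k, seed = seeds[si, t])
        nmi(cl, sim$true_labels)
      }, numeric(1))
      row <- row + 1L
      out[[row]] <- data.frame(method = methods, sigma = sigmas[si],
                               trial = t, nmi = unname(nmis))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
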