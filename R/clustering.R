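#' Cluster assignment container
#'
#' @param sample_ids character sample identifiers.
#' @param labels integer cluster labels in `1..k`.
#' @param k number of clusters (default: `max(labels)`).
#' @return A list of class `cluster_assignment`. Empty clusters (labels in
#'   `1..k` that no sample carries) are recorded in the `empty_clusters`
#'   field.
#' @export
cluster_assignment <- function(sample_ids, labels, k = max(labels)) {
  sample_ids <- as.character(sample_ids)
  labels <- as.integer(labels)
  stopifnot(length(sample_ids) == length(labels))
  if (any(labels < 1L | labels > k))
    stopf("labels must lie in 1..%d", k)
  structure(list(sample_ids = sample_ids, labels = labels, k = as.integer(k),
                 empty_clusters = setdiff(seq_len(k), unique(labels))),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d samples, k = %d; sizes: %s\n",
              length(x$labels), x$k,
              paste(tabulate(x$labels, x$k), collapse = "/")))
  invisible(x)
}

labels_of <- function(x) {
  if (inherits(x, "cluster_assignment")) x$labels else as.integer(x)
}

# connected components of the graph whose edges are the strictly positive
# off-diagonal entries of W (label propagation)
n_components <- function(W) {
  n <- nrow(W)
  adj <- W > 0
  diag(adj) <- TRUE
  comp <- integer(n)
  ncomp <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    ncomp <- ncomp + 1L
    frontier <- s
    comp[s] <- ncomp
    while (length(frontier)) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & comp == 0L)
      comp[nb] <- ncomp
      frontier <- nb
    }
  }
  ncomp
}

# symmetric normalized Laplacian L = I - D^{-1/2} W D^{-1/2};
# isolated samples (zero degree) keep a unit diagonal entry
normalized_laplacian <- function(W) {
  W <- as_similarity_matrix(W)
  d <- rowSums(W)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  L <- diag(nrow(W)) - W * tcrossprod(dinv)
  (L + t(L)) / 2
}

#' Spectral clustering of a similarity matrix
#'
#' Normalized spectral clustering: eigenvectors of the k smallest
#' eigenvalues of the symmetric normalized Laplacian, rows scaled to unit
#' length, then k-means with a fixed seed and 20 restarts.
#'
#' @param W symmetric nonnegative similarity matrix or `fused_similarity`.
#' @param k number of clusters, `2 <= k < n`.
#' @param seed RNG seed for the k-means restarts.
#' @param nstart k-means restarts.
#' @return A [cluster_assignment()].
#' @export
spectral_cluster <- function(W, k, seed = 1, nstart = 20) {
  Wm <- as_similarity_matrix(W)
  n <- nrow(Wm)
  stopifnot(k >= 2, k < n)
  L <- normalized_laplacian(Wm)
  eig <- eigen(L, symmetric = TRUE)
  ncomp <- n_components(Wm)
  if (ncomp > k)
    warnf("similarity graph has %d connected components but k = %d", ncomp, k)
  U <- eig$vectors[, n - seq_len(k) + 1L, drop = FALSE]  # k smallest
  rn <- sqrt(rowSums(U^2))
  rn[rn == 0] <- 1
  U <- U / rn
  # idealized inputs (exact planted blocks) can yield duplicated embedding
  # rows, which k-means rejects as indistinct centers; a vanishing seeded
  # jitter makes rows distinct without moving any real structure
  km <- with_seed(seed, {
    Uj <- U + matrix(stats::rnorm(length(U), 0, 1e-10), nrow(U))
    stats::kmeans(Uj, centers = k, nstart = nstart, iter.max = 100)
  })
  ids <- rownames(Wm) %||% paste0("S", seq_len(n))
  cluster_assignment(ids, km$cluster, k)
}

#' Monti-style consensus clustering
#'
#' Repeatedly subsamples the cohort, spectrally clusters the induced
#' sub-similarity, and records for every sample pair the fraction of
#' co-sampled runs in which it co-clustered. Final labels come from
#' average-linkage hierarchical clustering of `1 - consensus` cut at k
#' (optionally by re-running spectral clustering on the consensus matrix).
#'
#' @inheritParams spectral_cluster
#' @param reps number of subsampled clustering rounds (>= 2).
#' @param subsample_fraction fraction of samples drawn per round, in (0, 1].
#' @param final `"hclust"` (default) or `"spectral"`: how the consensus
#'   matrix is turned into final labels.
#' @return A list with `consensus` (n x n matrix in `[0,1]`, diagonal 1),
#'   `assignment` (a [cluster_assignment()]), `reps`, `subsample_fraction`.
#' @export
consensus_cluster <- function(W, k, reps = 100, subsample_fraction = 0.8,
                              seed = 1, final = c("hclust", "spectral")) {
  final <- match.arg(final)
  Wm <- as_similarity_matrix(W)
  n <- nrow(Wm)
  stopifnot(reps >= 2, subsample_fraction > 0, subsample_fraction <= 1)
  m <- max(2L, round(subsample_fraction * n))
  co_cluster <- matrix(0, n, n)
  co_sample <- matrix(0, n, n)
  seeds <- derive_seeds(seed, reps)
  for (r in seq_len(reps)) {
    idx <- if (m >= n) seq_len(n)
           else with_seed(seeds[r], sort(sample.int(n, m)))
    sub <- spectral_cluster(Wm[idx, idx, drop = FALSE], k, seed = seeds[r])
    lab <- sub$labels
    ind <- outer(lab, lab, "==") * 1
    co_cluster[idx, idx] <- co_cluster[idx, idx] + ind
    co_sample[idx, idx] <- co_sample[idx, idx] + 1
  }
  never <- co_sample == 0
  if (any(never & upper.tri(never)))
    warnf("%d sample pairs were never co-sampled; consensus imputed as 0",
          sum(never & upper.tri(never)))
  consensus <- ifelse(co_sample > 0, co_cluster / co_sample, 0)
  diag(consensus) <- 1
  dimnames(consensus) <- dimnames(Wm)
  ids <- rownames(Wm) %||% paste0("S", seq_len(n))
  assignment <- if (final == "hclust") {
    hc <- stats::hclust(stats::as.dist(1 - consensus), method = "average")
    cluster_assignment(ids, stats::cutree(hc, k), k)
  } else {
    spectral_cluster(consensus, k, seed = seed)
  }
  list(consensus = consensus, assignment = assignment, reps = reps,
       subsample_fraction = subsample_fraction)
}

#' Eigengap heuristic for choosing the cluster count
#'
#' Returns the k in `2..k_max` maximizing the gap between consecutive
#' eigenvalues of the symmetric normalized Laplacian. When no gap dominates
#' (e.g. a structureless uniform similarity) the estimate falls back to 2
#' with `confident = FALSE`.
#'
#' @inheritParams spectral_cluster
#' @param k_max largest k considered (`< n`).
#' @return List with `k`, `gaps` (named vector over `2..k_max`), `confident`.
#' @export
eigengap_estimate <- function(W, k_max) {
  Wm <- as_similarity_matrix(W)
  n <- nrow(Wm)
  stopifnot(k_max >= 2, k_max < n)
  lam <- sort(eigen(normalized_laplacian(Wm), symmetric = TRUE,
                    only.values = TRUE)$values)
  ks <- 2:k_max
  gaps <- lam[ks + 1L] - lam[ks]
  names(gaps) <- ks
  best <- which.max(gaps)
  sorted <- sort(gaps, decreasing = TRUE)
  second <- if (length(sorted) > 1L) sorted[2L] else 0
  confident <- sorted[1L] > 2 * max(second, 1e-12)
  list(k = ks[best], gaps = gaps, confident = confident)
}
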