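#' Affinity construction parameters
#'
#' @param K neighbourhood size for the local affinity and kernel bandwidth;
#'   `NULL` (default) resolves to `max(2, round(n/10))` capped at `n - 1`
#'   once the cohort size n is known.
#' @param mu dimensionless bandwidth multiplier of the scaled exponential
#'   kernel; sensible range 0.3--0.8, default 0.5.
#' @return A list of class `affinity_config`.
#' @export
affinity_config <- function(K = NULL, mu = 0.5) {
  stopifnot(mu > 0, is.null(K) || K >= 1)
  structure(list(K = K, mu = mu), class = "affinity_config")
}

resolve_K <- function(K, n) {
  K <- K %||% max(2L, round(n / 10))
  K <- as.integer(min(K, n - 1L))
  if (K < 1L) stopf("need K >= 1 (n = %d)", n)
  K
}

#' Euclidean distances between samples
#'
#' @param layer an [omics_layer()] with complete values, or a plain numeric
#'   matrix (samples in rows).
#' @return Symmetric n x n distance matrix with zero diagonal.
#' @export
pairwise_distances <- function(layer) {
  X <- if (inherits(layer, "omics_layer")) layer$values else as.matrix(layer)
  if (anyNA(X)) stopf("distance computation requires complete values")
  as.matrix(stats::dist(X, method = "euclidean"))
}

#' Scaled exponential similarity kernel
#'
#' Converts a distance matrix into a dense similarity
#' `P(i,j) = exp(-D(i,j)^2 / (mu * eps_ij))` with locally adaptive bandwidth
#' `eps_ij = (mean_K(i) + mean_K(j) + D(i,j)) / 3`, where `mean_K(i)` is the
#' mean distance from sample i to its K nearest neighbours. The diagonal is
#' exactly 1 and the matrix is symmetric.
#'
#' @param D symmetric nonnegative distance matrix with zero diagonal.
#' @param K neighbour count for the bandwidth (default `max(2, round(n/10))`).
#' @param mu bandwidth multiplier (> 0).
#' @return Symmetric kernel affinity matrix with unit diagonal.
#' @export
scaled_exponential_kernel <- function(D, K = NULL, mu = 0.5) {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(n == ncol(D), mu > 0)
  if (max(abs(D - t(D))) > 1e-8) stopf("distance matrix must be symmetric")
  K <- resolve_K(K, n)
  # mean distance from each sample to its K nearest neighbours (self excluded)
  mean_knn <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    mean(sort(d)[seq_len(K)])
  }, numeric(1))
  eps <- (outer(mean_knn, mean_knn, "+") + D) / 3
  if (any(eps <= 0)) {
    warnf("zero kernel bandwidth for some pairs (duplicate points); flooring at 1e-12")
    eps[eps <= 0] <- 1e-12
  }
  P <- exp(-D^2 / (mu * eps))
  P <- (P + t(P)) / 2
  diag(P) <- 1
  dimnames(P) <- dimnames(D)
  P
}

#' KNN-restricted, row-normalized local affinity
#'
#' For every sample, keeps only the K largest off-diagonal kernel
#' similarities (ties broken toward the lower sample index), zeroes the rest
#' and the diagonal, and normalizes each row to sum to 1. The result is
#' generally asymmetric; no downstream step may assume otherwise.
#'
#' @param P kernel affinity matrix (see [scaled_exponential_kernel()]).
#' @param K neighbours retained per row (default `max(2, round(n/10))`).
#' @return Row-stochastic sparse-support local affinity matrix with
#'   attribute `K`.
#' @export
knn_local_affinity <- function(P, K = NULL) {
  P <- as.matrix(P)
  n <- nrow(P)
  stopifnot(n == ncol(P))
  K <- resolve_K(K, n)
  S <- matrix(0, n, n, dimnames = dimnames(P))
  for (i in seq_len(n)) {
    cand <- setdiff(order(-P[i, ], seq_len(n)), i)  # stable: ties -> lower index
    nb <- cand[seq_len(K)]
    S[i, nb] <- P[i, nb]
    rs <- sum(S[i, ])
    if (rs > 0) S[i, ] <- S[i, ] / rs
  }
  attr(S, "K") <- K
  S
}

#' Binary support mask of a local affinity
#'
#' `mask(i,j) = 1` where `S(i,j) != 0`; the mask restricts the path-0 fit of
#' the fused similarity to the observed neighbour edges of each layer.
#'
#' @param S local affinity matrix.
#' @return Binary matrix of the same dimension.
#' @export
support_mask <- function(S) {
  M <- (as.matrix(S) != 0) * 1
  dimnames(M) <- dimnames(S)
  M
}

#' Per-layer affinities for a multi-omics dataset
#'
#' Runs distances, kernel and KNN restriction for every layer.
#'
#' @param dataset a [multi_omics()] object.
#' @param K,mu see [affinity_config()].
#' @return A list with `P_list` (kernel affinities), `S_list` (local
#'   affinities), `mask_list` (support masks), and `K`.
#' @export
build_affinities <- function(dataset, K = NULL, mu = 0.5) {
  stopifnot(inherits(dataset, "multi_omics"))
  n <- nrow(dataset$layers[[1L]]$values)
  K <- resolve_K(K, n)
  P_list <- lapply(dataset$layers, function(l)
    scaled_exponential_kernel(pairwise_distances(l), K = K, mu = mu))
  S_list <- lapply(P_list, knn_local_affinity, K = K)
  list(P_list = P_list, S_list = S_list,
       mask_list = lapply(S_list, support_mask), K = K)
}
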