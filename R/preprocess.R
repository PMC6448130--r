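#' Drop features with excessive missingness
#'
#' Removes every feature whose fraction of missing values across samples is
#' strictly greater than `max_missing_rate` (default 20%, the usual omics
#' screening threshold).
#'
#' @param layer an [omics_layer()].
#' @param max_missing_rate maximum tolerated missing fraction in `[0, 1]`.
#' @return The layer restricted to surviving features; sample order unchanged.
#' @export
filter_missing <- function(layer, max_missing_rate = 0.2) {
  stopifnot(inherits(layer, "omics_layer"),
            max_missing_rate >= 0, max_missing_rate <= 1)
  rate <- colMeans(is.na(layer$values))
  keep <- rate <= max_missing_rate
  if (!any(keep))
    stopf("layer '%s': all %d features exceed missing rate %.0f%%",
          layer$layer_name, ncol(layer$values), 100 * max_missing_rate)
  omics_layer(layer$values[, keep, drop = FALSE],
              layer_name = layer$layer_name)
}

# pairwise sample distances under missingness: squared differences over
# mutually observed features, scaled by the shared-feature count
# (root mean squared difference). Inf when two samples share no feature.
missing_aware_distances <- function(X) {
  obs <- !is.na(X)
  X0 <- X
  X0[!obs] <- 0
  obs <- obs * 1
  shared <- obs %*% t(obs)
  sq <- (X0^2) %*% t(obs)
  d2 <- sq + t(sq) - 2 * tcrossprod(X0)
  d2[d2 < 0] <- 0  # numeric round-off
  d <- sqrt(ifelse(shared > 0, d2 / shared, Inf))
  diag(d) <- 0
  d
}

#' Impute missing entries by K-nearest-neighbour averaging
#'
#' Each missing cell (sample i, feature j) is filled with the mean of
#' feature j over the `k_neighbors` samples closest to i, where closeness is
#' Euclidean distance over mutually observed features scaled by the number of
#' shared features. Neighbours that themselves miss feature j are skipped;
#' if none of the k neighbours observes j, the overall observed feature mean
#' is used (with a warning).
#'
#' @param layer an [omics_layer()]; every feature must have at least one
#'   observed value (run [filter_missing()] first).
#' @param k_neighbors number of neighbours to average over (default 10).
#' @return The layer with no missing entries.
#' @export
knn_impute <- function(layer, k_neighbors = 10) {
  stopifnot(inherits(layer, "omics_layer"), k_neighbors >= 1)
  X <- layer$values
  if (!anyNA(X)) return(layer)
  n <- nrow(X)
  all_missing <- colSums(!is.na(X)) == 0L
  if (any(all_missing))
    stopf("layer '%s': feature(s) fully missing (%s); filter them first",
          layer$layer_name,
          paste(utils::head(colnames(X)[all_missing], 3L), collapse = ", "))
  k <- min(k_neighbors, n - 1L)
  D <- missing_aware_distances(X)
  col_means <- colMeans(X, na.rm = TRUE)
  used_fallback <- FALSE
  for (i in which(rowSums(is.na(X)) > 0L)) {
    ord <- order(D[i, ])
    nb <- setdiff(ord, i)[seq_len(k)]
    for (j in which(is.na(X[i, ]))) {
      v <- X[nb, j]
      v <- v[!is.na(v)]
      if (length(v) == 0L) {
        X[i, j] <- col_means[j]
        used_fallback <- TRUE
      } else {
        X[i, j] <- mean(v)
      }
    }
  }
  if (used_fallback)
    warnf("layer '%s': some cells had no neighbour observing the feature; used feature mean",
          layer$layer_name)
  omics_layer(X, layer_name = layer$layer_name)
}

#' Z-score each feature across samples
#'
#' Centers each feature to mean 0 and scales to standard deviation 1, using
#' the population convention (divide by n). Zero-variance features map to
#' all-zero columns.
#'
#' @param layer an [omics_layer()] with no missing values.
#' @return The normalized layer.
#' @export
zscore_normalize <- function(layer) {
  stopifnot(inherits(layer, "omics_layer"))
  X <- layer$values
  if (anyNA(X)) stopf("layer '%s': impute missing values before normalizing",
                      layer$layer_name)
  mu <- colMeans(X)
  sd <- sqrt(colMeans(X^2) - mu^2)
  sd[sd < .Machine$double.eps^0.5] <- Inf  # constant columns -> zeros
  Z <- sweep(sweep(X, 2L, mu), 2L, sd, "/")
  omics_layer(Z, layer_name = layer$layer_name)
}

#' Keep the most variable features
#'
#' Retains the `n_keep` features with the largest (population) standard
#' deviation; ties are broken by original feature order. The common
#' dimension-reduction step for dense platforms such as methylation arrays
#' (e.g. keeping the 1,000 most variable CpG sites).
#'
#' @param layer an [omics_layer()].
#' @param n_keep number of features to retain; if `n_keep >= p` the layer is
#'   returned unchanged.
#' @return The layer restricted to the selected features, in their original
#'   column order.
#' @export
top_variable_features <- function(layer, n_keep) {
  stopifnot(inherits(layer, "omics_layer"), n_keep >= 1)
  p <- ncol(layer$values)
  if (n_keep >= p) return(layer)
  sds <- apply(layer$values, 2L, sd_pop)
  keep <- sort(order(-sds, seq_len(p))[seq_len(n_keep)])
  omics_layer(layer$values[, keep, drop = FALSE],
              layer_name = layer$layer_name)
}

#' Standard preprocessing chain for one omics layer
#'
#' Missingness filter, KNN imputation, feature-variance screen, then
#' z-normalization, in that order.
#'
#' @inheritParams filter_missing
#' @inheritParams knn_impute
#' @param n_keep retain this many most-variable features; `NULL` keeps all.
#' @return The preprocessed layer.
#' @export
preprocess_layer <- function(layer, max_missing_rate = 0.2, k_neighbors = 10,
                             n_keep = NULL) {
  layer <- filter_missing(layer, max_missing_rate)
  layer <- knn_impute(layer, k_neighbors)
  if (!is.null(n_keep)) layer <- top_variable_features(layer, n_keep)
  zscore_normalize(layer)
}
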