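#' MCFS: multi-cluster feature scores against a fused similarity
#'
#' Back-projects the global similarity structure onto one layer's original
#' features. The k nontrivial smallest-eigenvalue eigenvectors of the
#' symmetric normalized Laplacian of W form a spectral embedding of the
#' cluster structure; each embedding direction is regressed on the layer's
#' (z-scored) features with an L1 penalty, and a feature's score is the
#' largest absolute coefficient it attains across the embedding directions.
#' Features that never enter any sparse regression score 0.
#'
#' @param W fused similarity (`fused_similarity` or matrix) over the layer's
#'   samples.
#' @param layer an [omics_layer()] with samples matching W.
#' @param k_clusters number of embedding directions (the presumed cluster
#'   count), `2 <= k_clusters < n`.
#' @param target_cardinality approximate number of nonzero coefficients per
#'   embedding regression; default `min(75, p, (n - 1) / 2)` — five times
#'   the usual 15-feature report size, capped so the lasso never saturates
#'   (a saturated fit has unstable coefficients and meaningless scores).
#'   Ignored when `l1_lambda` is given.
#' @param l1_lambda optional fixed lasso penalty; overrides
#'   `target_cardinality`.
#' @return A list of class `feature_ranking`: `feature_ids`, `scores`
#'   (nonnegative), `layer_name`.
#' @export
mcfs_scores <- function(W, layer, k_clusters, target_cardinality = NULL,
                        l1_lambda = NULL) {
  stopifnot(inherits(layer, "omics_layer"))
  Wm <- as_similarity_matrix(W)
  n <- nrow(Wm)
  if (nrow(layer$values) != n)
    stopf("layer has %d samples but W is %d x %d", nrow(layer$values), n, n)
  if (!is.null(rownames(Wm)) &&
      !identical(rownames(Wm), sample_ids(layer)))
    stopf("sample ids of W and layer disagree")
  if (k_clusters < 2 || k_clusters >= n)
    stopf("need 2 <= k_clusters < n")
  p <- ncol(layer$values)
  target_cardinality <- target_cardinality %||%
    max(1L, min(75L, p, floor((n - 1) / 2)))

  # spectral embedding: skip the trivial bottom eigenvector
  L <- normalized_laplacian(Wm)
  eig <- eigen(L, symmetric = TRUE)
  Y <- eig$vectors[, n - 1L - seq_len(k_clusters) + 1L, drop = FALSE]

  # z-score features; zero-variance columns become zeros and can never
  # enter the lasso path
  X <- zscore_normalize(layer)$values
  scores <- numeric(p)
  for (j in seq_len(k_clusters)) {
    fit <- glmnet::glmnet(X, Y[, j], alpha = 1, standardize = FALSE,
                          intercept = TRUE,
                          dfmax = max(target_cardinality + 10L, 20L))
    cf <- if (!is.null(l1_lambda)) {
      as.numeric(glmnet::coef.glmnet(fit, s = l1_lambda, exact = FALSE))[-1L]
    } else {
      # lambda on the path whose active-set size is closest to the target
      # (ties resolved toward the larger penalty / sparser model)
      dfs <- fit$df
      pick <- which.min(abs(dfs - target_cardinality))
      as.numeric(fit$beta[, pick])
    }
    scores <- pmax(scores, abs(cf))
  }
  structure(list(feature_ids = feature_ids(layer), scores = scores,
                 layer_name = layer$layer_name),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("<feature_ranking '%s'> %d features, %d with nonzero score\n",
              x$layer_name, length(x$scores), sum(x$scores > 0)))
  invisible(x)
}

#' Select the top-scoring features from a ranking
#'
#' @param ranking a `feature_ranking` from [mcfs_scores()].
#' @param n_top number of features to return (all features if
#'   `n_top >= p`); ties broken by original feature order.
#' @return Character vector of feature ids, highest score first.
#' @export
select_top_features <- function(ranking, n_top = 15) {
  stopifnot(inherits(ranking, "feature_ranking"), n_top >= 1)
  p <- length(ranking$scores)
  ord <- order(-ranking$scores, seq_len(p))
  ranking$feature_ids[ord[seq_len(min(n_top, p))]]
}
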