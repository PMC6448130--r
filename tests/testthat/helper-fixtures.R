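# shared fixture builders; everything is generated in code at test time

# C random KNN local affinities on n points (k-dimensional Gaussian cloud)
random_affinities <- function(n, C, seed, K = 3, dim = 3) {
  set.seed(seed)
  lapply(seq_len(C), function(i) {
    X <- matrix(rnorm(n * dim), n)
    P <- scaled_exponential_kernel(pairwise_distances(X), K = K)
    knn_local_affinity(P, K = K)
  })
}

# exact block-diagonal similarity with the given block sizes
planted_block_W <- function(sizes, within = 1, between = 0) {
  lab <- rep(seq_along(sizes), sizes)
  W <- matrix(between, length(lab), length(lab))
  for (b in seq_along(sizes)) W[lab == b, lab == b] <- within
  diag(W) <- within
  attr(W, "labels") <- lab
  W
}

# small, fast synthetic benchmark config (scaled-down cohort and features)
small_sim_config <- function(seed = 1, noise_sd = 1, ...) {
  sim_config(n_samples = 60, n_clusters = 4,
             layer_specs = list(
               layer_spec(80, list(c(1L, 2L)), name = "a"),
               layer_spec(80, list(c(2L, 3L)), name = "b"),
               layer_spec(40, list(c(3L, 4L)), name = "c")),
             noise_sd = noise_sd, seed = seed, ...)
}

# one planted cluster-indicator feature among pure-noise features, plus the
# matching block similarity (with generic jitter so the Laplacian spectrum
# is non-degenerate)
make_planted_layer <- function(seed, n_per = 20, p_noise = 49, dup_noise = FALSE) {
  set.seed(seed)
  lab <- rep(1:2, each = n_per)
  n <- length(lab)
  planted <- (lab == 2) + rnorm(n, 0, 0.1)
  noise <- matrix(rnorm(n * p_noise), n, p_noise)
  vals <- cbind(planted = planted, noise)
  colnames(vals) <- c("planted", paste0("noise", seq_len(p_noise)))
  if (dup_noise) {
    vals <- cbind(vals, noise_dup = vals[, "noise1"])
  }
  W <- planted_block_W(c(n_per, n_per), within = 1, between = 0.02)
  J <- matrix(runif(n * n, 0, 0.01), n, n)
  W <- W + (J + t(J)) / 2
  list(layer = omics_layer(vals), W = W, lab = lab)
}

# independent entropy-formula NMI oracle (contingency-table arithmetic,
# written without reference to the package implementation)
oracle_nmi <- function(a, b) {
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  mi <- 0
  for (x in ua) for (y in ub) {
    pxy <- sum(a == x & b == y) / n
    if (pxy > 0)
      mi <- mi + pxy * log(pxy / ((sum(a == x) / n) * (sum(b == y) / n)))
  }
  ent <- function(l) {
    p <- table(l) / length(l)
    -sum(p * log(p))
  }
  ha <- ent(a); hb <- ent(b)
  if (ha + hb == 0) return(1)
  mi / ((ha + hb) / 2)
}
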