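test_that("planted labels follow the requested proportions", {
  cfg <- sim_config(n_samples = 200, seed = 2)
  sim <- simulate_multiomics(cfg)
  expect_equal(unname(tabulate(sim$true_labels$labels, 4)), rep(50L, 4))

  cfg2 <- small_sim_config(seed = 2, cluster_proportions = c(0.4, 0.3, 0.2, 0.1))
  sizes <- tabulate(simulate_multiomics(cfg2)$true_labels$labels, 4)
  expect_true(all(abs(sizes - c(24, 18, 12, 6)) <= 1))
  expect_equal(sum(sizes), 60)

  expect_equal(length(sim$dataset$layers), 3)
  expect_equal(ncol(sim$dataset$layers[[3]]$values), 200)
})

test_that("zero noise with distinct means gives perfect single-layer recovery", {
  cfg <- sim_config(n_samples = 60, noise_sd = 0,
                    layer_specs = list(layer_spec(50, name = "clean")),
                    seed = 4)
  sim <- simulate_multiomics(cfg)
  X <- sim$dataset$layers[[1]]
  # same-cluster samples are identical at zero noise, so the adaptive
  # bandwidth hits its floor (with a warning) and recovery is still exact
  expect_warning(
    P <- scaled_exponential_kernel(pairwise_distances(X), K = 6),
    "bandwidth")
  cl <- spectral_cluster(P, 4, seed = 1)
  expect_equal(nmi(cl, sim$true_labels), 1)
})

test_that("a merging layer is capped at the analytic NMI of its merged partition", {
  # 4 equal clusters of 50; layer merges {3,4}: the best any clustering of
  # that layer can do is the merged partition itself
  truth <- rep(1:4, each = 50)
  merged <- c(1, 2, 3, 3)[truth]
  analytic <- oracle_nmi(truth, merged)
  # closed form: MI = H(merged) = 1.5 log 2; mean entropy = 1.75 log 2
  expect_equal(analytic, 1.5 / 1.75, tolerance = 1e-12)
  expect_equal(nmi(truth, merged), analytic, tolerance = 1e-12)

  expect_warning(
    cfg <- sim_config(n_samples = 200, noise_sd = 1, seed = 8,
                      layer_specs = list(layer_spec(300, list(c(3L, 4L))))),
    "merged in every layer")
  sim <- simulate_multiomics(cfg)
  X <- zscore_normalize(sim$dataset$layers[[1]])
  P <- scaled_exponential_kernel(pairwise_distances(X), K = 20)
  for (seed in 1:5) {
    cl <- spectral_cluster(P, 4, seed = seed)
    expect_lte(nmi(cl, sim$true_labels), analytic + 1e-9)
  }
})

test_that("generation is bit-identical under a fixed seed and varies otherwise", {
  cfg <- small_sim_config(seed = 99, fuzzy_fraction = 0.15)
  a <- simulate_multiomics(cfg)
  b <- simulate_multiomics(cfg)
  expect_identical(a$dataset$layers[[1]]$values, b$dataset$layers[[1]]$values)
  expect_identical(a$true_labels$labels, b$true_labels$labels)

  cfg2 <- small_sim_config(seed = 100, fuzzy_fraction = 0.15)
  c <- simulate_multiomics(cfg2)
  expect_false(identical(a$dataset$layers[[1]]$values,
                         c$dataset$layers[[1]]$values))
})

test_that("invalid merge maps and unseparable configs are caught", {
  expect_error(sim_config(layer_specs = list(layer_spec(10, list(c(1L, 9L))))),
               "outside")
  expect_warning(sim_config(layer_specs = list(layer_spec(10, list(c(1L, 2L))))),
                 "merged in every layer")
})

test_that("SVD seeding preserves feature count and column geometry", {
  # a real-ish seeding matrix with correlated features
  set.seed(77)
  base <- matrix(rnorm(40 * 6), 40, 6) %*% matrix(rnorm(6 * 30), 6, 30)
  cfg <- sim_config(n_samples = 50, noise_sd = 0,
                    layer_specs = list(layer_spec(30, n_components = 5)),
                    seed = 7)
  sim <- svd_seed_layers(list(base), cfg)
  Y <- sim$dataset$layers[[1]]$values
  expect_equal(ncol(Y), 30)

  # at zero noise the generated layer lives in the seeding matrix's
  # leading right-singular space
  v_real <- svd(base)$v[, 1:5]
  v_gen <- svd(Y)$v[, 1:3]
  proj <- crossprod(v_real, v_gen)   # 5 x 3 alignment matrix
  cano <- sqrt(colSums(proj^2))      # cosines of principal angles
  expect_true(all(cano > 0.9))

  expect_error(
    svd_seed_layers(list(base),
                    sim_config(n_samples = 50,
                               layer_specs = list(layer_spec(30, n_components = 20)),
                               seed = 7)),
    "rank")
})

test_that("identity projection reduces SVD seeding to the plain generator", {
  cfg <- sim_config(n_samples = 30, noise_sd = 0.5,
                    layer_specs = list(layer_spec(12), layer_spec(8)),
                    fuzzy_fraction = 0.2, seed = 31)
  plain <- simulate_multiomics(cfg)
  proj <- list(list(loadings = diag(12), scales = rep(1, 12), feature_ids = NULL),
               list(loadings = diag(8), scales = rep(1, 8), feature_ids = NULL))
  seeded <- hopes:::simulate_core(cfg, proj)
  expect_equal(seeded$dataset$layers[[1]]$values,
               plain$dataset$layers[[1]]$values, ignore_attr = TRUE)
  expect_equal(seeded$dataset$layers[[2]]$values,
               plain$dataset$layers[[2]]$values, ignore_attr = TRUE)
})

test_that("noise_sweep returns a tidy seeded table that degrades with noise", {
  cfg <- small_sim_config(seed = 6)
  res <- noise_sweep(cfg, sigmas = c(0.5, 4), trials = 4,
                     methods = c("snf", "layer1"), K = 6)
  expect_equal(nrow(res), 2 * 4 * 2)
  expect_setequal(unique(res$method), c("snf", "layer1"))
  expect_true(all(res$nmi >= 0 & res$nmi <= 1))

  med <- aggregate(nmi ~ method + sigma, res, median)
  for (m in unique(med$method)) {
    v <- med$nmi[med$method == m][order(med$sigma[med$method == m])]
    expect_true(all(diff(v) <= 1e-9))
  }

  res2 <- noise_sweep(cfg, sigmas = c(0.5, 4), trials = 4,
                      methods = c("snf", "layer1"), K = 6)
  expect_identical(res, res2)  # fully seeded
  expect_error(noise_sweep(cfg, 1, 2, methods = "layer9"), "unknown method")
})
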