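test_that("hopes_energy matches a naive term-by-term evaluation", {
  set.seed(21)
  S <- random_affinities(5, 2, seed = 21, K = 2)
  M <- lapply(S, support_mask)
  W <- matrix(rnorm(25), 5, 5)
  alpha <- 0.7; beta <- 1.3

  # independent naive-loop oracle
  fro2 <- function(A) sum(A^2)
  e <- 0
  for (i in 1:2) {
    e <- e + fro2(W * M[[i]] - S[[i]])
    e <- e + alpha * fro2(W - S[[i]] %*% W)
    for (j in 1:2) e <- e + beta * fro2(W - S[[i]] %*% W %*% t(S[[j]]))
  }
  expect_equal(hopes_energy(W, S, M, alpha, beta), e, tolerance = 1e-12)

  # exact fit on support, alpha = beta = 0 -> zero energy
  Wfit <- S[[1]]
  expect_equal(hopes_energy(Wfit, S[1], M[1], 0, 0), 0)

  expect_gte(hopes_energy(matrix(rnorm(25), 5), S, M, 1, 1), 0)
  expect_error(hopes_energy(matrix(0, 4, 4), S, M), "must be")
})

test_that("consensus ADMM agrees with the direct Kronecker oracle", {
  for (seed in 1:3) {
    S <- random_affinities(12, 2 + seed %% 2, seed = seed)
    cfg <- fusion_config(alpha = 1, beta = 1)
    fit <- hopes_fuse(S, config = cfg, trace = FALSE)
    W_star <- direct_solve_oracle(S, config = cfg)
    rel <- sqrt(sum((fit$W_raw - W_star)^2)) / sqrt(sum(W_star^2))
    expect_lt(rel, 1e-5)
    expect_true(fit$converged)
  }
})

test_that("oracle solution satisfies first-order optimality", {
  S <- random_affinities(10, 2, seed = 33)
  cfg <- fusion_config(alpha = 0.5, beta = 0.8)
  W_star <- direct_solve_oracle(S, config = cfg)
  g <- hopes:::hopes_energy_gradient(W_star, S, alpha = cfg$alpha,
                                     beta = cfg$beta, ridge = cfg$ridge)
  expect_lt(sqrt(sum(g^2)), 1e-8 * 10)
  expect_error(direct_solve_oracle(random_affinities(70, 2, seed = 1)),
               "n <= 64")
})

test_that("single-layer path-0 limit reproduces the masked closed form", {
  S <- random_affinities(9, 1, seed = 8, K = 3)
  M <- lapply(S, support_mask)
  cfg <- fusion_config(alpha = 0, beta = 0, ridge = 1e-8)
  fit <- hopes_fuse(S, M, cfg, trace = FALSE)
  # on support W = S / (1 + ridge) ~ S; off support ~ 0
  expect_lt(max(abs(fit$W_raw[M[[1]] == 1] - S[[1]][M[[1]] == 1])), 1e-6)
  expect_lt(max(abs(fit$W_raw[M[[1]] == 0])), 1e-6)
  # direct oracle agrees in the same limit
  W_star <- direct_solve_oracle(S, M, cfg)
  expect_equal(fit$W_raw, W_star, tolerance = 1e-6)
})

test_that("fusion energy decreases from the initialization and W is a valid affinity", {
  S <- random_affinities(15, 3, seed = 5)
  fit <- hopes_fuse(S, config = fusion_config(), trace = TRUE)
  W_init <- Reduce(`+`, S) / 3
  e0 <- hopes_energy(W_init, S, alpha = 0.01, beta = 1)
  expect_lte(tail(fit$energy_trace, 1), e0)
  expect_true(all(is.finite(fit$energy_trace)))

  W <- fit$matrix
  expect_lt(max(abs(W - t(W))), 1e-10)
  expect_true(all(W >= 0))
  expect_equal(diag(W), apply(W, 1, max), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(length(fit$diagnostics$primal_residuals),
               fit$diagnostics$iterations_used)
})

test_that("strict convexity: different initializations reach the same solution", {
  S <- random_affinities(12, 2, seed = 17)
  cfg <- fusion_config()
  f1 <- hopes_fuse(S, config = cfg, trace = FALSE)
  set.seed(99)
  f2 <- hopes_fuse(S, config = cfg, trace = FALSE,
                   W0 = matrix(rnorm(144), 12, 12))
  expect_lt(max(abs(f1$W_raw - f2$W_raw)), 10 * cfg$tol)
})

test_that("hopes_fuse is sample-permutation equivariant", {
  S <- random_affinities(12, 2, seed = 13)
  set.seed(13)
  perm <- sample(12)
  Sp <- lapply(S, function(s) {
    out <- s[perm, perm]
    attr(out, "K") <- attr(s, "K")
    out
  })
  f <- hopes_fuse(S, config = fusion_config(), trace = FALSE)
  fp <- hopes_fuse(Sp, config = fusion_config(), trace = FALSE)
  expect_equal(fp$W_raw, f$W_raw[perm, perm], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("raising beta does not add fused edges supported by a single layer", {
  # planted two-layer fixtures; count surviving post-clamp entries whose
  # support comes from exactly one layer, at low vs high path-2 weight
  count_lo <- count_hi <- 0
  for (seed in 1:10) {
    S <- random_affinities(30, 2, seed = 100 + seed, K = 4)
    M <- lapply(S, support_mask)
    single <- (M[[1]] + M[[2]]) == 1
    W_lo <- hopes_fuse(S, M, fusion_config(beta = 0.1), trace = FALSE)$matrix
    W_hi <- hopes_fuse(S, M, fusion_config(beta = 2), trace = FALSE)$matrix
    count_lo <- count_lo + sum(W_lo[single] > 1e-8)
    count_hi <- count_hi + sum(W_hi[single] > 1e-8)
  }
  expect_lte(count_hi, count_lo)
})

test_that("snf_step equals the hand-computed sandwich product", {
  S <- rbind(c(0, 0.7, 0.3), c(0.4, 0, 0.6), c(0.5, 0.5, 0))
  P_avg <- rbind(c(0.5, 0.3, 0.2), c(0.3, 0.5, 0.2), c(0.2, 0.2, 0.6))
  # hand expansion of S %*% P_avg %*% t(S), element by element
  hand <- matrix(0, 3, 3)
  for (m in 1:3) for (n in 1:3)
    for (k in 1:3) for (l in 1:3)
      hand[m, n] <- hand[m, n] + S[m, k] * P_avg[k, l] * S[n, l]
  expect_equal(snf_step(S, P_avg), hand, tolerance = 1e-12)
})

test_that("snf_fuse output is symmetric and preserves planted block structure", {
  sizes <- c(6, 6)
  lab <- rep(1:2, sizes)
  set.seed(30)
  X <- matrix(rnorm(12 * 4, mean = 3 * lab), 12, 4)
  P <- scaled_exponential_kernel(pairwise_distances(X), K = 3)
  S <- knn_local_affinity(P, K = 3)
  fit <- snf_fuse(list(P, P), list(S, S), iterations = 5)
  W <- fit$matrix
  expect_equal(W, t(W), tolerance = 1e-12)
  within <- mean(W[outer(lab, lab, "==") & row(W) != col(W)])
  between <- mean(W[outer(lab, lab, "!=")])
  expect_gt(within, 5 * between)

  expect_error(snf_fuse(list(P), list(S)), "at least two layers")
})
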