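#' Fusion solver parameters
#'
#' The three weights play different roles and live on different scales: the
#' path-0 fit acts only on the ~n*K support edges of each layer, while every
#' path-1/path-2 term acts on all n^2 entries of W. Because any row-stochastic
#' local affinity leaves constant matrices invariant, large `alpha`/`beta`
#' drive the minimizer toward a flat, structureless W, and a vanishing
#' `ridge` lets the filtration terms fill the off-support background with
#' that same flat level. The defaults (`alpha = 0.01`, `beta = 1`,
#' `ridge = 5`) were calibrated once on the package's synthetic benchmark:
#' a small `alpha`, a `beta` large enough that edges lacking cross-layer
#' support are suppressed, and a `ridge` strong enough to shrink unsupported
#' background similarity toward zero while barely moving the anchored
#' support entries (whose curvature is set by the layer count, not by
#' `ridge`). See the methods vignette for the calibration rationale.
#'
#' @param alpha weight of the path-1 (one-hop filtration) terms, >= 0.
#' @param beta weight of the path-2 (two-hop, cross-layer) terms, >= 0.
#' @param ridge Tikhonov weight; makes the objective strictly convex and
#'   shrinks entries outside every layer's neighbour support toward zero.
#' @param rho ADMM penalty parameter, > 0.
#' @param max_iter maximum ADMM iterations.
#' @param tol stopping tolerance on the primal/dual residuals.
#' @param seed kept for interface symmetry; the solver is deterministic.
#' @return A list of class `fusion_config`.
#' @export
fusion_config <- function(alpha = 0.01, beta = 1, ridge = 5, rho = 5,
                          max_iter = 500, tol = 1e-7, seed = NULL) {
  stopifnot(alpha >= 0, beta >= 0, ridge >= 0, rho > 0,
            max_iter >= 1, tol > 0)
  structure(list(alpha = alpha, beta = beta, ridge = ridge, rho = rho,
                 max_iter = as.integer(max_iter), tol = tol, seed = seed),
            class = "fusion_config")
}

check_fusion_inputs <- function(S_list, mask_list) {
  if (length(S_list) < 1L) stopf("need at least one local affinity")
  n <- nrow(S_list[[1L]])
  for (S in S_list)
    if (!is.matrix(S) || nrow(S) != n || ncol(S) != n)
      stopf("all local affinities must be %d x %d matrices", n, n)
  for (M in mask_list)
    if (!is.matrix(M) || nrow(M) != n || ncol(M) != n)
      stopf("all masks must be %d x %d matrices", n, n)
  if (length(mask_list) != length(S_list))
    stopf("mask list length (%d) must equal affinity list length (%d)",
          length(mask_list), length(S_list))
  n
}

#' Path-0/1/2 fusion energy
#'
#' Evaluates, for a candidate global similarity W and per-layer local
#' affinities S_i with support masks M_i,
#' \deqn{\sum_i \|W \odot M_i - S_i\|_F^2 + \alpha \|W - S_i W\|_F^2 +
#'       \beta \sum_j \|W - S_i W S_j^T\|_F^2.}
#' The path-0 term anchors W to each layer's observed neighbour edges, the
#' path-1 term asks W to be stable under one-hop filtration through each
#' layer, and the path-2 term demands support from every ordered pair of
#' layers. The ridge regularizer is never folded into this value.
#'
#' @param W candidate n x n matrix.
#' @param S_list list of local affinity matrices (one per layer).
#' @param mask_list list of binary support masks; defaults to the nonzero
#'   patterns of `S_list`.
#' @param alpha,beta term weights.
#' @return The scalar energy (>= 0).
#' @export
hopes_energy <- function(W, S_list, mask_list = lapply(S_list, support_mask),
                         alpha = 1, beta = 1) {
  n <- check_fusion_inputs(S_list, mask_list)
  if (!is.matrix(W) || nrow(W) != n || ncol(W) != n)
    stopf("W must be %d x %d", n, n)
  e <- 0
  SW <- lapply(S_list, function(S) S %*% W)
  for (i in seq_along(S_list)) {
    e <- e + sum((W * mask_list[[i]] - S_list[[i]])^2)
    if (alpha > 0) e <- e + alpha * sum((W - SW[[i]])^2)
    if (beta > 0)
      for (j in seq_along(S_list))
        e <- e + beta * sum((W - tcrossprod(SW[[i]], S_list[[j]]))^2)
  }
  e
}

# gradient of hopes_energy plus the ridge term, used for optimality checks
hopes_energy_gradient <- function(W, S_list,
                                  mask_list = lapply(S_list, support_mask),
                                  alpha = 1, beta = 1, ridge = 0) {
  n <- check_fusion_inputs(S_list, mask_list)
  G <- 2 * ridge * W
  for (i in seq_along(S_list)) {
    Si <- S_list[[i]]
    G <- G + 2 * (W * mask_list[[i]] - Si) * mask_list[[i]]
    if (alpha > 0) {
      R <- W - Si %*% W
      G <- G + 2 * alpha * (R - crossprod(Si, R))
    }
    if (beta > 0) {
      for (j in seq_along(S_list)) {
        Sj <- S_list[[j]]
        R <- W - Si %*% W %*% t(Sj)
        G <- G + 2 * beta * (R - crossprod(Si, R %*% Sj))
      }
    }
  }
  G
}

# conjugate gradient for the path-2 proximal system
#   [2*beta*(C^2 X - A X A' - A' X A + G X G) + rho X] = RHS
# with A = sum_i S_i and G = sum_i S_i' S_i; SPD operator, matrix-free.
cg_path2 <- function(RHS, A, G, C, beta, rho, X0, rtol = 1e-10,
                     maxit = 1000L) {
  op <- function(X)
    2 * beta * (C^2 * X - A %*% X %*% t(A) - crossprod(A, X %*% A) +
                  G %*% X %*% G) + rho * X
  X <- X0
  R <- RHS - op(X)
  P <- R
  rs <- sum(R * R)
  bnorm <- sqrt(sum(RHS * RHS))
  if (bnorm == 0) return(X * 0)
  for (it in seq_len(maxit)) {
    if (sqrt(rs) <= rtol * bnorm) break
    Q <- op(P)
    a <- rs / sum(P * Q)
    X <- X + a * P
    R <- R - a * Q
    rs_new <- sum(R * R)
    P <- R + (rs_new / rs) * P
    rs <- rs_new
  }
  X
}

#' Fuse per-layer local affinities into one global similarity
#'
#' Minimizes the path-0/1/2 energy (see [hopes_energy()]) plus a tiny ridge
#' by consensus ADMM: one block fits W to every layer's support edges
#' (solved elementwise in closed form), one block per layer enforces one-hop
#' stability (a cached Cholesky solve in `2*alpha*(I-S_i)'(I-S_i) + rho*I`),
#' and one block enforces all pairwise two-hop constraints (conjugate
#' gradient on the Kronecker normal equations, warm-started). After
#' convergence the iterate is symmetrized, negatives are clamped to zero and
#' the diagonal is set to each row's maximum (self-similarity convention) so
#' that the result is a valid spectral-clustering affinity.
#'
#' @param S_list list of local affinity matrices, one per omics layer.
#' @param mask_list binary support masks; default: nonzero patterns of
#'   `S_list`.
#' @param config a [fusion_config()].
#' @param trace record the fusion energy at every iteration (costs a few
#'   matrix products per iteration; disable for large sweeps).
#' @param W0 optional starting point; default is the mean of `S_list`. Since
#'   the objective is strictly convex, the solution is initialization
#'   independent (up to the stopping tolerance).
#' @return An object of class `fused_similarity`: list with `matrix`
#'   (post-processed W), `W_raw` (the unconstrained minimizer before
#'   post-processing), `energy_trace`, `converged`, `method = "hopes"`, and
#'   `diagnostics` (primal/dual residuals, iterations used, final energy).
#' @export
hopes_fuse <- function(S_list, mask_list = lapply(S_list, support_mask),
                       config = fusion_config(), trace = TRUE, W0 = NULL) {
  stopifnot(inherits(config, "fusion_config"))
  n <- check_fusion_inputs(S_list, mask_list)
  C <- length(S_list)
  alpha <- config$alpha; beta <- config$beta
  rho <- config$rho; ridge <- config$ridge
  ids <- rownames(S_list[[1L]])

  # precomputations shared across iterations
  mask_sum <- Reduce(`+`, mask_list)
  s_sum <- Reduce(`+`, lapply(seq_len(C), function(i)
    S_list[[i]] * mask_list[[i]]))          # S_i restricted to its support
  s_sum <- matrix(as.numeric(s_sum), n, n)  # drop stray attributes
  A2 <- Reduce(`+`, S_list)                 # path-2 operator pieces
  G2 <- Reduce(`+`, lapply(S_list, crossprod))
  use_p1 <- alpha > 0
  use_p2 <- beta > 0
  n_blocks <- 1L + if (use_p1) C else 0L
  n_blocks <- n_blocks + if (use_p2) 1L else 0L

  chol_p1 <- if (use_p1) lapply(S_list, function(S) {
    M <- diag(n) - S
    chol(2 * alpha * crossprod(M) + rho * diag(n))
  }) else NULL

  W <- W0 %||% (Reduce(`+`, S_list) / C)    # initialization: mean affinity
  W <- matrix(as.numeric(W), n, n)
  X <- rep(list(W), n_blocks)
  U <- rep(list(matrix(0, n, n)), n_blocks)
  energy <- if (trace)
    hopes_energy(W, S_list, mask_list, alpha, beta) else NULL
  r_hist <- s_hist <- numeric(0)
  converged <- FALSE
  denom0 <- 2 * mask_sum + rho              # path-0 elementwise denominator

  for (it in seq_len(config$max_iter)) {
    b <- 1L
    # path-0 block: elementwise quadratic over all layer supports
    V <- W - U[[b]]
    X[[b]] <- (2 * s_sum + rho * V) / denom0
    b <- b + 1L
    if (use_p1) {
      for (i in seq_len(C)) {
        V <- W - U[[b]]
        R <- chol_p1[[i]]
        X[[b]] <- backsolve(R, forwardsolve(t(R), rho * V))
        b <- b + 1L
      }
    }
    if (use_p2) {
      V <- W - U[[b]]
      X[[b]] <- cg_path2(rho * V, A2, G2, C, beta, rho, X0 = X[[b]])
    }

    W_old <- W
    acc <- Reduce(`+`, Map(`+`, X, U))
    W <- rho * acc / (2 * ridge + n_blocks * rho)
    for (b in seq_len(n_blocks)) U[[b]] <- U[[b]] + X[[b]] - W

    r <- sqrt(sum(vapply(X, function(x) sum((x - W)^2), numeric(1))))
    s <- rho * sqrt(n_blocks) * sqrt(sum((W - W_old)^2))
    r_hist <- c(r_hist, r); s_hist <- c(s_hist, s)
    if (trace)
      energy <- c(energy, hopes_energy(W, S_list, mask_list, alpha, beta))

    x_norm <- sqrt(sum(vapply(X, function(x) sum(x^2), numeric(1))))
    u_norm <- sqrt(sum(vapply(U, function(u) sum(u^2), numeric(1))))
    eps_pri <- sqrt(n_blocks) * n * config$tol +
      config$tol * max(x_norm, sqrt(n_blocks) * sqrt(sum(W^2)))
    eps_dual <- sqrt(n_blocks) * n * config$tol + config$tol * rho * u_norm
    if (r <= eps_pri && s <= eps_dual) { converged <- TRUE; break }
  }
  if (!converged)
    warnf("consensus ADMM did not reach tol %.1e in %d iterations; returning best iterate",
          config$tol, config$max_iter)

  W_raw <- W
  Wp <- (W + t(W)) / 2
  Wp[Wp < 0] <- 0
  diag(Wp) <- apply(Wp, 1L, max)
  dimnames(Wp) <- dimnames(W_raw) <- list(ids, ids)

  structure(list(
    matrix = Wp, W_raw = W_raw, sample_ids = ids,
    energy_trace = energy, converged = converged, method = "hopes",
    diagnostics = list(primal_residuals = r_hist, dual_residuals = s_hist,
                       iterations_used = length(r_hist),
                       final_energy = hopes_energy(W_raw, S_list, mask_list,
                                                   alpha, beta),
                       config = config)),
    class = "fused_similarity")
}

#' @export
print.fused_similarity <- function(x, ...) {
  cat(sprintf("<fused_similarity method=%s> %d x %d, %s\n",
              x$method, nrow(x$matrix), ncol(x$matrix),
              if (isTRUE(x$converged)) "converged" else "not converged"))
  invisible(x)
}

#' Direct dense solver for the fusion objective (verification oracle)
#'
#' Builds the full normal equations of the path-0/1/2 energy plus ridge in
#' `vec(W)` using Kronecker products and solves them with a dense linear
#' solve. The system is n^2 x n^2, so this is restricted to n <= 64 and is
#' intended for verifying [hopes_fuse()] on small instances, not for
#' production use.
#'
#' @inheritParams hopes_fuse
#' @return The n x n unconstrained minimizer (no post-processing applied).
#' @export
direct_solve_oracle <- function(S_list,
                                mask_list = lapply(S_list, support_mask),
                                config = fusion_config()) {
  n <- check_fusion_inputs(S_list, mask_list)
  if (n > 64) stopf("direct oracle limited to n <= 64 (got n = %d)", n)
  C <- length(S_list)
  alpha <- config$alpha; beta <- config$beta
  In <- diag(n); I2 <- diag(n^2)
  A <- config$ridge * I2
  b <- numeric(n^2)
  for (i in seq_len(C)) {
    Si <- S_list[[i]]
    A <- A + diag(as.vector(mask_list[[i]]))
    b <- b + as.vector(S_list[[i]] * mask_list[[i]])
    if (alpha > 0) {
      M1 <- I2 - kronecker(In, Si)
      A <- A + alpha * crossprod(M1)
    }
    if (beta > 0) {
      for (j in seq_len(C)) {
        M2 <- I2 - kronecker(S_list[[j]], Si)
        A <- A + beta * crossprod(M2)
      }
    }
  }
  W <- matrix(solve(A, b), n, n)
  dimnames(W) <- dimnames(S_list[[1L]])
  W
}

# one raw similarity-network-fusion update for a single layer:
# the layer's local affinity sandwiching the average status matrix of the
# remaining layers
#' Single SNF update step
#'
#' Computes `S %*% P_avg %*% t(S)`: the similarity between two samples is
#' replaced by the average similarity (taken from the other layers) between
#' their K nearest neighbours in this layer.
#'
#' @param S local affinity of the layer being updated.
#' @param P_avg average status matrix of the other layers.
#' @return The updated (un-normalized) status matrix.
#' @export
snf_step <- function(S, P_avg) S %*% P_avg %*% t(S)

# SNF row normalization: half the probability mass on the diagonal,
# the rest spread row-stochastically over the off-diagonal entries
snf_normalize <- function(P) {
  off <- P
  diag(off) <- 0
  rs <- rowSums(off)
  rs[rs == 0] <- 1
  Pn <- off / (2 * rs)
  diag(Pn) <- 0.5
  Pn
}

#' Similarity network fusion (baseline)
#'
#' The message-passing baseline: each layer's status matrix is iteratively
#' replaced by its local affinity sandwiching the average of the other
#' layers' status matrices, re-normalized after every step; the fused result
#' is the symmetrized average of the final status matrices.
#'
#' @param P_list list of kernel affinity matrices (one per layer, C >= 2).
#' @param S_list list of matching local affinities.
#' @param iterations number of update sweeps (default 20).
#' @return A `fused_similarity` with `method = "snf"`.
#' @export
snf_fuse <- function(P_list, S_list, iterations = 20) {
  if (length(P_list) < 2L)
    stopf("SNF requires at least two layers (the update averages the others)")
  if (length(S_list) != length(P_list))
    stopf("P_list and S_list must have the same length")
  C <- length(P_list)
  n <- nrow(P_list[[1L]])
  ids <- rownames(P_list[[1L]])
  P <- lapply(P_list, snf_normalize)
  for (t in seq_len(iterations)) {
    P_new <- vector("list", C)
    for (v in seq_len(C)) {
      avg <- Reduce(`+`, P[-v]) / (C - 1)
      P_new[[v]] <- snf_normalize(snf_step(S_list[[v]], avg))
    }
    P <- P_new
  }
  W <- Reduce(`+`, P) / C
  W <- (W + t(W)) / 2
  dimnames(W) <- list(ids, ids)
  structure(list(matrix = W, W_raw = W, sample_ids = ids,
                 energy_trace = NULL, converged = TRUE, method = "snf",
                 diagnostics = list(iterations_used = iterations)),
            class = "fused_similarity")
}
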