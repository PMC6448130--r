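---
title: "Methods: path-elucidated similarity fusion for multi-omics cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: path-elucidated similarity fusion for multi-omics cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A tumor cohort measured on several omics layers (expression, methylation,
miRNA, ...) poses an integration problem: layers differ in dimension by
orders of magnitude, in scale, and in which subtypes they can resolve.
`hopes` works entirely in *patient-similarity space*: each layer is reduced
to an n×n similarity network, and the networks are fused into a single
global similarity `W`. Everything downstream — spectral clustering into
subtypes, survival comparison, feature back-projection — consumes `W`.

## Per-layer affinities

Each preprocessed layer (missingness filter at 20%, K-nearest-neighbour
imputation, optional top-variable-feature screen, per-feature z-scoring
with the population sd convention) yields:

* a dense kernel affinity `P(i,j) = exp(-D(i,j)^2 / (mu * eps_ij))`, with
  the locally adaptive bandwidth
  `eps_ij = (mean_K(i) + mean_K(j) + D(i,j)) / 3`, where `mean_K(i)` is the
  mean distance from sample i to its K nearest neighbours. `mu` defaults to
  0.5 (sensible range 0.3–0.8). For z-scored high-dimensional layers the
  exponent scales with `sqrt(p)`, so off-diagonal kernel values can be
  numerically tiny; all downstream steps depend only on their relative
  magnitudes, which double precision preserves down to extremely small
  values (underflow would require p beyond roughly 10^4 features, above the
  package's intended dense-matrix scale).
* the local affinity `S_i`: each row keeps its K largest off-diagonal
  kernel values (ties broken toward the lower sample index), the diagonal
  is zero, and rows are normalized to sum to one. `S_i` is deliberately
  asymmetric; nothing downstream assumes otherwise.
* the binary support mask `Omega_i`, the nonzero pattern of `S_i`. The
  mask is read as the indicator of *observed neighbour edges*: the fused
  matrix is compared with `S_i` only where the layer actually expressed a
  neighbour relation. (The opposite reading — masking to the zero pattern —
  would leave the data fit with no attraction term at all and make `W = 0`
  optimal, so it cannot be the intended one.)

`K` defaults to `max(2, round(n/10))`, capped at `n - 1`: neighbourhood
size should grow with cohort size but stay a small fraction of it.

## The fusion energy

`hopes_fuse()` minimizes, over unconstrained real `W`,

```
sum_i ( ||W . Omega_i - S_i||_F^2            # path-0: fit observed edges
      + alpha * ||W - S_i W||_F^2            # path-1: one-hop stability
      + beta  * sum_j ||W - S_i W S_j'||_F^2 # path-2: pairwise support
      ) + lambda * ||W||_F^2                 # ridge
```

`.` is the elementwise product (a matrix product would void the masking
role of `Omega`). Inside the path-1/2 terms, `S_i` is the *local* (KNN)
affinity, not the full kernel: the filtration idea is that an edge of `W`
should survive being routed through each layer's neighbourhood graph, and
only the KNN-truncated matrix encodes that graph.

The solution is symmetrized, negatives are clamped to zero, and the
diagonal is set to each row's maximum. The energy leaves the diagonal
weakly determined, and spectral clustering needs dominant self-similarity,
so the diagonal convention is a post-processing choice, not part of the
optimization.

### Why the default weights are what they are

The three term families act on very different entry counts: each path-0
term touches only the ~nK support edges of one layer, while every path-1
and path-2 term touches all n² entries of `W`. Two consequences, both
verified against an exact solver during development:

1. Because every row-stochastic `S_i` leaves constant matrices invariant,
   the filtration terms are *minimized by flat matrices*. With weights of
   order one they overwhelm the path-0 anchor and the exact minimizer is
   essentially constant — structureless.
2. With a vanishing ridge, entries outside every layer's support have
   almost no curvature, and the filtration terms fill that background with
   the same flat level as the anchored edges, erasing the contrast spectral
   clustering needs.

The defaults were therefore calibrated once on the synthetic benchmark and
frozen: `alpha = 0.01` (path-1 stability as a gentle smoother),
`beta = 1` (path-2 is the discriminative term: it is what suppresses edges
lacking cross-layer support), and `lambda = 5` (shrinks unsupported
background similarity toward zero; the anchored support entries have
curvature set by the layer count and barely move). All three are exposed,
and the weights deserve re-calibration if the affinity convention (K, the
kernel) changes materially.

### The solver

The objective is a strictly convex quadratic; `hopes_fuse()` uses consensus
ADMM with one block per term family:

* path-0 block: closed-form elementwise update,
* one block per layer for path-1: a cached Cholesky solve in
  `2*alpha*(I - S_i)'(I - S_i) + rho*I`,
* one path-2 block: matrix-free conjugate gradient on the normal equations,
  warm-started across iterations (the operator collapses all C² pairs into
  four matrix products via `A = sum_i S_i` and `G = sum_i S_i'S_i`).

Stopping uses the standard primal/dual residual criterion with
`tol = 1e-7` (the returned iterate is then within ~1e-6 relative Frobenius
of the exact minimizer on the shipped test instances) and `rho = 5`, chosen
for iteration count on well-conditioned instances (tens of iterations at
n = 200). `direct_solve_oracle()` builds the full n²×n² Kronecker normal
equations and solves them densely; it is restricted to n ≤ 64 and exists so
the tests can verify the ADMM against an independent route.

## SNF baseline

`snf_fuse()` implements the classical similarity-network-fusion update
`P(v) <- S(v) %*% avg(P(others)) %*% t(S(v))` with the usual status-matrix
normalization (half the mass on the diagonal, the rest row-stochastic),
simultaneous updates, 20 iterations by default, and a final symmetrized
average. `snf_step()` exposes one raw sandwich product so the update can be
checked against hand arithmetic.

## Clustering and evaluation

`spectral_cluster()` is normalized spectral clustering (symmetric
normalized Laplacian, k smallest eigenvectors, unit-normalized rows,
seeded k-means with 20 restarts). Exactly duplicated embedding rows — which
arise only for idealized block-constant inputs — receive a vanishing seeded
jitter (sd 1e-10) because k-means rejects indistinct centers.
`consensus_cluster()` follows the Monti resampling convention
(100 reps, 80% subsampling by default) and cuts the average-linkage tree of
`1 - consensus` at k; re-running spectral clustering on the consensus
matrix is available as an option. `eigengap_estimate()` suggests k by the
largest Laplacian eigengap and flags the estimate as low-confidence when no
gap dominates (best gap below twice the runner-up).

NMI uses natural logarithms and normalizes by the arithmetic mean of the
label entropies (max- and sqrt-mean variants are exposed; published NMI
values can shift by a few hundredths across conventions). Accuracy is
computed under the label permutation maximizing agreement, found
exhaustively (cluster labels are arbitrary). The χ² test is Pearson's
without continuity correction; the log-rank test and Kaplan–Meier curves
are delegated to the `survival` package, with an independent at-risk-table
computation serving as the oracle in the tests.

## MCFS feature back-projection

`mcfs_scores()` regresses each of the k nontrivial smallest-eigenvalue
eigenvectors of the Laplacian of `W` (the same Laplacian the clustering
uses) on a layer's z-scored features with an L1 penalty (`glmnet` lasso
path), picking the path point whose active set is closest to the target
cardinality (default `min(75, p, (n-1)/2)`: five times the usual
15-feature report, capped so the fit never saturates — a saturated lasso
has unstable coefficients and meaningless scores). A feature's score is
its largest absolute coefficient across
eigenvectors; zero-variance features can never enter the path and score 0.

## The synthetic benchmark

`simulate_multiomics()` plants k clusters (default 4 × 50 samples) observed
through layers of 500/500/200 features — echoing the expression /
methylation / miRNA dimension asymmetry at desk scale. Each layer carries a
`merge_map`: the true clusters it cannot distinguish (they share a mean
vector). The default three layers merge pairs {1,2}, {2,3} and {3,4}, so
every layer alone is "indivisible" for one pair while every pair is
separable in some layer — the configuration that makes fusion necessary.
Cluster means are drawn N(0, signal²) per feature with signal 1.5, noise is
i.i.d. N(0, σ²) with σ ∈ {1, 2, 3} as the low/moderate/high grid, and a
fuzzy variant interpolates a fraction of "edge" samples (default 15% at mix
0.4) toward a neighbouring cluster's mean. `svd_seed_layers()` can replace
the i.i.d. feature geometry with the leading right-singular structure of a
user-supplied real matrix, so generated layers inherit realistic feature
correlations; tests use synthetic stand-ins for the seeding matrices.

What the generator does *not* emulate: count/beta-value marginal
distributions, feature–feature correlation (unless SVD-seeded), batch
effects, and — importantly — noise that corrupts a layer's *own* cluster
structure. With hundreds of i.i.d.-noise features, σ up to 3 leaves each
layer's KNN graph essentially intact (each layer stays at the analytic NMI
ceiling of its merged partition, 6/7 for one merged pair of four equal
clusters). Benchmark conclusions therefore speak to the *integration* of
complementary, individually reliable layers, not to robustness under
layer-destroying noise.

## Known limitations

* Being a quadratic model anchored to the raw affinities, the fused `W`
  retains a weakened trace of single-layer edges; in the information-
  complete regime above, the multiplicative SNF diffusion can reach exact
  recovery while HOPES typically leaves a handful of boundary samples
  misassigned (median NMI ≈ 0.91–0.96 across the noise grid in the
  acceptance run, versus 1.0 for SNF). The fused-vs-single-layer margin,
  not the fused-vs-SNF margin, is the robust effect at these conditions.
* Dense n×n linear algebra throughout: intended for cohorts up to a few
  thousand samples, not for n ≥ 10⁴.
* `alpha`, `beta`, `lambda` are calibrated for row-stochastic KNN
  affinities; other affinity conventions require re-calibration.
* The label-matching accuracy is exhaustive over permutations and limited
  to 8 cluster labels.

## Problem sizes used by the shipped tests

Unit tests run on cohorts of 3–60 samples; the end-to-end and benchmark
checks use the full default generator (200 samples, 3 layers, 20 trials
per noise level), and solver-vs-oracle checks use n = 12 where the dense
n²×n² oracle is cheap. The acceptance script reruns the benchmark at
σ = 1, 2, 3 with 20 trials each.
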