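#' Coreness template vector
#'
#' Sorted template of continuous coreness scores,
#' `C*_m = 1 / (1 + exp(-(m - beta*n) * tan(pi*alpha/2)))` for m = 1..n.
#' `alpha` controls the sharpness of the core-periphery boundary (0 is
#' maximally fuzzy, values near 1 approach a binary split) and `beta` the
#' size of the core. `alpha` is clipped just below 1 to avoid the tangent
#' singularity.
#'
#' @param n number of nodes.
#' @param alpha sharpness parameter in `[0, 0.999]`.
#' @param beta core-size parameter in `[0, 1]`.
#' @return nondecreasing length-n template with values in (0, 1).
#' @export
core_shape <- function(n, alpha, beta) {
  alpha <- min(max(alpha, 0), 0.999)
  m <- seq_len(n)
  1 / (1 + exp(-(m - beta * n) * tan(pi * alpha / 2)))
}

#' Core quality of a coreness assignment
#'
#' `R = sum_{i != j} G_ij C_i C_j` for a normalized coreness vector
#' (`sum(C) = 1`, hence `sum_ij C_i C_j = 1`). The diagonal of G is
#' excluded.
#'
#' @param g nonnegative square interaction matrix (e.g. predictor pair
#'   counts).
#' @param coreness normalized coreness vector.
#' @return scalar quality R.
#' @export
core_quality <- function(g, coreness) {
  if (abs(sum(coreness) - 1) > 1e-8) stop("coreness must be normalized to sum 1")
  g0 <- as_square_matrix(g)
  diag(g0) <- 0
  as.numeric(coreness %*% g0 %*% coreness)
}

#' Annealed coreness assignment
#'
#' Finds the permutation of the (normalized) coreness template that
#' maximizes the core quality R by Metropolis simulated annealing over pair
#' swaps with geometric cooling, taking the best of several restarts.
#' Deterministic given a seed.
#'
#' @inheritParams core_quality
#' @param alpha,beta template parameters, see [core_shape()].
#' @param restarts number of annealing restarts (default 25).
#' @param seed optional RNG seed.
#' @return list with `coreness` (normalized, best found), `quality`,
#'   `alpha`, `beta`.
#' @export
anneal_coreness <- function(g, alpha, beta, restarts = 25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g0 <- as_square_matrix(g)
  diag(g0) <- 0
  n <- nrow(g0)
  tmpl <- core_shape(n, alpha, beta)
  tmpl <- tmpl / sum(tmpl)
  res <- cpp_anneal_coreness(g0, tmpl, as.integer(restarts),
                             cooling = 0.95, per_temp = as.integer(25 * n),
                             patience = 15L, max_temps = 400L)
  cr <- as.numeric(res$coreness)
  list(coreness = cr, quality = core_quality(g0, cr),
       alpha = alpha, beta = beta)
}

#' Mean coreness profile over a parameter grid
#'
#' Anneals the coreness assignment at each point of a logarithmically spaced
#' grid of (alpha, beta) values, ranks parameter pairs by their maximized
#' quality R, and averages each node's normalized coreness over the top
#' fraction of pairs.
#'
#' @inheritParams anneal_coreness
#' @param grid_size number of grid values per parameter (default 51,
#'   log-spaced over `[0.01, 1]`, alpha clipped below 1).
#' @param top_fraction fraction of best parameter pairs aggregated (default
#'   0.05).
#' @return mean coreness vector with the full grid results (alpha, beta,
#'   quality) as attribute `"grid"`.
#' @export
coreness_profile <- function(g, grid_size = 51, top_fraction = 0.05,
                             restarts = 25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vals <- 10^seq(-2, 0, length.out = grid_size)
  alphas <- pmin(vals, 0.999)
  betas <- vals
  pairs <- expand.grid(alpha = alphas, beta = betas)
  n <- nrow(as_square_matrix(g))
  core_mat <- matrix(NA_real_, nrow(pairs), n)
  qual <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    fit <- anneal_coreness(g, pairs$alpha[k], pairs$beta[k], restarts = restarts)
    core_mat[k, ] <- fit$coreness
    qual[k] <- fit$quality
  }
  n_top <- max(1L, ceiling(top_fraction * nrow(pairs)))
  top <- order(qual, decreasing = TRUE)[seq_len(n_top)]
  out <- colMeans(core_mat[top, , drop = FALSE])
  attr(out, "grid") <- cbind(pairs, quality = qual)
  out
}
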