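#' Regional predictor-preference similarity
#'
#' Pearson correlation between the optimal-predictor frequency vectors of
#' every pair of regions (rows of the region x predictor frequency matrix).
#' The diagonal is zeroed.
#'
#' @param h region x predictor frequency matrix; rows sum to 1.
#' @return N x N symmetric similarity matrix.
#' @export
preference_similarity <- function(h) {
  if (any(abs(rowSums(h) - 1) > 1e-8)) stop("frequency rows must sum to 1")
  if (any(apply(h, 1, sd) == 0)) stop("zero-variance frequency row")
  s <- cor(t(h))
  diag(s) <- 0
  (s + t(s)) / 2
}

#' Modularity maximization with a uniform null (generalized Louvain)
#'
#' Optimizes `Q = sum_ij B_ij delta(sigma_i, sigma_j)` with
#' `B = S - gamma * P` and uniform null `P_ij = 1`, by a Louvain-style
#' greedy node-move / aggregation scheme operating directly on the signed
#' modularity matrix. Node order is randomized, so different seeds explore
#' different near-optima.
#'
#' @param s symmetric similarity matrix.
#' @param gamma resolution parameter; default is the mean off-diagonal
#'   similarity.
#' @param seed optional RNG seed.
#' @return list of class `"partition"`: `labels` (contiguous integers from
#'   1), `gamma`, `q`.
#' @export
modularity_louvain <- function(s, gamma = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- as_square_matrix(s)
  if (max(abs(s - t(s))) > 1e-10) stop("similarity matrix must be symmetric")
  n <- nrow(s)
  if (is.null(gamma)) gamma <- mean(s[upper.tri(s) | lower.tri(s)])
  b <- s - gamma
  diag(b) <- 0
  node_lab <- seq_len(n)
  bcur <- b
  repeat {
    lab <- louvain_pass(bcur)
    lab <- match(lab, unique(lab))
    if (max(lab) == nrow(bcur)) break  # no merges at this level
    node_lab <- lab[node_lab]
    bcur <- rowsum(t(rowsum(bcur, lab)), lab)
    diag(bcur) <- 0  # internal weight is a constant offset for further moves
    if (nrow(bcur) == 1L) break
  }
  node_lab <- match(node_lab, unique(node_lab))
  q <- sum(b[outer(node_lab, node_lab, "==")])
  structure(list(labels = node_lab, gamma = gamma, q = q), class = "partition")
}

# one Louvain level: greedy single-node moves until no move improves Q
louvain_pass <- function(b) {
  n <- nrow(b)
  lab <- seq_len(n)
  repeat {
    moved <- FALSE
    for (i in sample.int(n)) {
      gains <- rowsum(b[i, ], lab)  # sum of B[i, j] by community (B[i,i] = 0)
      cur <- as.character(lab[i])
      best <- rownames(gains)[which.max(gains)]
      if (best != cur && gains[best, 1] > gains[cur, 1] + 1e-12) {
        lab[i] <- as.integer(best)
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  lab
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition: %d communities over %d nodes (gamma = %.4g, Q = %.4g)\n",
              max(x$labels), length(x$labels), x$gamma, x$q))
  invisible(x)
}

# canonical relabeling (first occurrence order) for comparing partitions
canonical_labels <- function(lab) match(lab, unique(lab))

#' Consensus partition by iterated co-assignment clustering
#'
#' Runs the Louvain optimizer many times from random initial conditions,
#' computes the co-assignment probability matrix across runs, subtracts the
#' analytic expected co-assignment (from each run's community sizes, under
#' independent random permutation of labels), re-clusters the difference
#' matrix, and repeats until all runs agree on a single partition.
#'
#' @inheritParams modularity_louvain
#' @param n_runs number of optimizer runs per iteration (default 1000).
#' @param max_iter maximum consensus iterations before giving up.
#' @return list of class `"partition"` with additional element `n_iter`.
#' @export
consensus_partition <- function(s, gamma = NULL, n_runs = 1000, seed = NULL,
                                max_iter = 50) {
  if (!is.null(seed)) set.seed(seed)
  s <- as_square_matrix(s)
  n <- nrow(s)
  if (is.null(gamma)) gamma <- mean(s[upper.tri(s) | lower.tri(s)])
  target <- s
  g <- gamma
  for (iter in seq_len(max_iter)) {
    runs <- lapply(seq_len(n_runs), function(r) {
      canonical_labels(modularity_louvain(target, gamma = g)$labels)
    })
    if (all(vapply(runs, identical, logical(1), y = runs[[1]]))) {
      final <- runs[[1]]
      b <- s - gamma
      diag(b) <- 0
      q <- sum(b[outer(final, final, "==")])
      return(structure(list(labels = final, gamma = gamma, q = q,
                            n_iter = iter), class = "partition"))
    }
    co <- matrix(0, n, n)
    expected <- 0
    for (lab in runs) {
      co <- co + outer(lab, lab, "==")
      sizes <- tabulate(lab)
      expected <- expected + sum(sizes * (sizes - 1)) / (n * (n - 1))
    }
    co <- co / n_runs
    expected <- expected / n_runs
    target <- co
    g <- expected  # so B = co-assignment minus its expectation
  }
  stop(sprintf("consensus did not converge after %d iterations", max_iter))
}
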