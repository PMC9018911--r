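# Shared fixtures and independent oracles used across the suite.

fx <- fixture_graphs()

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# random connected weighted graph (distance-free), for property tests
random_graph <- function(n, p = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    a <- matrix(0, n, n)
    ut <- upper.tri(a)
    edge <- rbinom(sum(ut), 1, p)
    a[ut] <- edge * runif(sum(ut), 0.2, 2)
    a <- a + t(a)
    ok <- tryCatch({
      validate_connectivity(a, "structural")
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(validate_connectivity(a, "structural"))
  }
}

# truncated-series matrix exponential oracle
expm_series <- function(a, terms = 30) {
  out <- diag(nrow(a))
  term <- diag(nrow(a))
  for (p in seq_len(terms)) {
    term <- term %*% a / p
    out <- out + term
  }
  out
}

# vectorized Monte Carlo oracle for raw mean first passage times
mc_mfpt <- function(a, n_walks = 100000, seed = 1) {
  set.seed(seed)
  n <- nrow(a)
  p <- a / rowSums(a)
  cump <- t(apply(p, 1, cumsum))
  est <- matrix(NA_real_, n, n)
  se <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      pos <- rep(i, n_walks)
      steps <- numeric(n_walks)
      alive <- rep(TRUE, n_walks)
      s <- 0
      while (any(alive) && s < 5000) {
        s <- s + 1
        u <- runif(sum(alive))
        nxt <- max.col(outer(u, rep(1, n)) <= cump[pos[alive], , drop = FALSE],
                       ties.method = "first")
        pos[alive] <- nxt
        arrived <- alive
        arrived[alive] <- nxt == j
        steps[arrived] <- s
        alive[arrived] <- FALSE
      }
      est[i, j] <- mean(steps)
      se[i, j] <- sd(steps) / sqrt(n_walks)
    }
  }
  list(est = est, se = se)
}

# independent step-by-step greedy navigation oracle
nav_oracle <- function(sc, metric) {
  n <- nrow(sc)
  hops <- matrix(0, n, n)
  plen <- matrix(0, n, n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t) next
      visited <- rep(FALSE, n)
      visited[s] <- TRUE
      cur <- s
      nh <- 0
      np <- 0
      repeat {
        nb <- which(sc[cur, ] > 0)
        if (!length(nb)) { nh <- Inf; np <- Inf; break }
        nxt <- nb[which.min(metric[nb, t])]
        if (visited[nxt]) { nh <- Inf; np <- Inf; break }
        np <- np + metric[cur, nxt]
        nh <- nh + 1
        cur <- nxt
        if (cur == t) break
        visited[cur] <- TRUE
        if (nh > n) { nh <- Inf; np <- Inf; break }
      }
      hops[s, t] <- nh
      plen[s, t] <- np
    }
  }
  list(hops = hops, plen = plen)
}

# Moran's I spatial autocorrelation with inverse-distance weights
moran_i <- function(v, coords) {
  d <- as.matrix(dist(coords))
  w <- 1 / d
  diag(w) <- 0
  z <- v - mean(v)
  n <- length(v)
  (n / sum(w)) * sum(w * outer(z, z)) / sum(z^2)
}

# smooth Gaussian-process map on the sphere (exponential covariance)
gp_map_factory <- function(sphere, rho = 0.5) {
  ang <- acos(pmin(pmax(tcrossprod(sphere), -1), 1))
  ch <- chol(exp(-ang / rho) + 1e-8 * diag(nrow(sphere)))
  function() as.numeric(t(ch) %*% rnorm(nrow(sphere)))
}

# block-structured similarity matrix with planted communities
block_similarity <- function(n, k, within = 0.9, between = -0.1, noise = 0.05) {
  lab <- rep(seq_len(k), each = n %/% k)
  s <- matrix(between, n, n)
  for (c in seq_len(k)) s[lab == c, lab == c] <- within
  s <- s + matrix(rnorm(n * n, sd = noise), n, n)
  s <- (s + t(s)) / 2
  diag(s) <- 0
  list(s = s, labels = lab)
}
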