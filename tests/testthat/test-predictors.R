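test_that("flow graph matches its closed forms and conserves marginals", {
  # 2-node closed form at t = 1: off-diagonal (1 - exp(-2))/2
  expect_equal(flow_graph(fx$edge2$sc, 1)[1, 2], (1 - exp(-2)) / 2,
               tolerance = 1e-12)
  # t = 0 reduces to the diagonal strength matrix
  a0 <- flow_graph(fx$geo10$sc, 0)
  s <- rowSums(unclass(fx$geo10$sc))
  expect_equal(a0, diag(s), tolerance = 1e-10)
  # column marginals equal strengths at every Markov time; total conserved
  for (t in c(1, 2.5, 5, 10)) {
    at <- flow_graph(fx$geo10$sc, t)
    expect_equal(colSums(at), s, tolerance = 1e-9)
    expect_equal(at, t(at), tolerance = 1e-9)
    expect_equal(sum(at), sum(s), tolerance = 1e-9)
  }
  # long-time limit: stationary outer product s_i s_j / sum(s)
  k3 <- fx$k3$sc
  sk <- rowSums(unclass(k3))
  expect_equal(flow_graph(k3, 10), outer(sk, sk) / sum(sk), tolerance = 1e-3)
  # isolated node is an error
  iso <- matrix(0, 3, 3); iso[1, 2] <- iso[2, 1] <- 1
  expect_error(flow_graph(iso, 1), "isolated")
})

test_that("navigation agrees with a step-by-step greedy oracle", {
  # complete graph: one hop at the Euclidean distance for every pair
  nav <- navigation(fx$k3$sc, fx$k3$geometry)
  euc <- euclidean_matrix(fx$k3$geometry)
  expect_equal(unclass(nav$nav_num), matrix(1, 3, 3) - diag(3))
  expect_equal(unclass(nav$nav_ms), euc, tolerance = 1e-12)
  # collinear chain: hop count equals the index gap
  nav3 <- navigation(fx$path3$sc, fx$path3$geometry)
  expect_equal(nav3$nav_num[1, 3], 2)
  expect_equal(nav3$nav_num[1, 2], 1)
  # constructed trap: navigating 2 -> 4 greedily steps into node 3, whose
  # only exit revisits node 2, so the route fails with Inf in both outputs
  coords <- rbind(c(0, 0, 1), c(60, 0, 1), c(50, 0, 1), c(100, 0, 1))
  a <- matrix(0, 4, 4)
  a[1, 2] <- a[2, 1] <- 1
  a[2, 3] <- a[3, 2] <- 1
  a[1, 4] <- a[4, 1] <- 1
  trap <- navigation(validate_connectivity(a, "structural"),
                     parcel_geometry(coords))
  expect_true(is.infinite(trap$nav_num[2, 4]))
  expect_true(is.infinite(trap$nav_ms[2, 4]))
  # exact oracle agreement (including failures) on geometric graphs
  graphs <- list(fx$geo10)
  for (seed in 1:3) {
    set.seed(seed)
    n <- 12
    pts <- matrix(rnorm(3 * n, sd = 20), n, 3)
    d <- as.matrix(dist(pts))
    a <- (d < quantile(d[upper.tri(d)], 0.25)) * 1
    diag(a) <- 0
    mst <- commCouple:::prim_mst(d)
    a[mst] <- 1
    a[mst[, 2:1]] <- 1
    a <- ((a + t(a)) > 0) * 1
    graphs[[length(graphs) + 1]] <-
      list(sc = validate_connectivity(a, "structural"),
           geometry = parcel_geometry(pts))
  }
  for (g in graphs) {
    res <- navigation(g$sc, g$geometry)
    met <- euclidean_matrix(g$geometry)
    orc <- nav_oracle(unclass(g$sc), met)
    expect_equal(unclass(res$nav_num), (orc$hops + t(orc$hops)) / 2)
    expect_equal(unclass(res$nav_ms), (orc$plen + t(orc$plen)) / 2,
                 tolerance = 1e-12)
  }
})

test_that("communicability equals the matrix exponential series", {
  expect_equal(communicability(fx$edge2$sc, "binary")[1, 2], sinh(1),
               tolerance = 1e-12)
  expect_equal(communicability(fx$edge2$sc, "binary")[1, 1], cosh(1),
               tolerance = 1e-12)
  g <- random_graph(8, seed = 11)
  a <- (unclass(g) > 0) * 1
  expect_equal(communicability(g, "binary"), expm_series(a), tolerance = 1e-8)
  s <- rowSums(unclass(g))
  an <- unclass(g) / outer(sqrt(s), sqrt(s))
  expect_equal(communicability(g, "weighted"), expm_series(an), tolerance = 1e-8)
})

test_that("matching index matches set and weight-sum brute force", {
  # two leaves of a star share exactly the hub
  m <- matching_index(fx$star5$sc, "binary")
  expect_equal(m[2, 3], 1)
  # path endpoints share the middle node; disjoint profiles score 0
  mp <- matching_index(fx$path3$sc, "binary")
  expect_equal(mp[1, 3], 1)     # both connect only to node 2
  expect_equal(mp[1, 2], 0)     # neighborhoods excluding the pair are disjoint
  # brute force both variants on a random weighted graph
  g <- unclass(random_graph(9, seed = 5))
  b <- (g > 0) * 1
  mb <- matching_index(g, "binary")
  mw <- matching_index(g, "weighted")
  for (i in 1:8) for (j in (i + 1):9) {
    gi <- setdiff(which(b[i, ] > 0), c(i, j))
    gj <- setdiff(which(b[j, ] > 0), c(i, j))
    inter <- intersect(gi, gj); uni <- union(gi, gj)
    expect_equal(mb[i, j], if (length(uni)) length(inter) / length(uni) else 0,
                 tolerance = 1e-12)
    num <- sum(g[i, inter] + g[j, inter])
    den <- sum(g[i, uni] + g[j, uni])
    expect_equal(mw[i, j], if (den > 0) num / den else 0, tolerance = 1e-12)
  }
  expect_true(all(mw >= 0 & mw <= 1))
})

test_that("shortest paths match hand evaluation and igraph", {
  # 5-node path graph, binary: endpoints at hop distance 4
  a <- matrix(0, 5, 5)
  for (i in 1:4) a[i, i + 1] <- a[i + 1, i] <- 1
  sp <- shortest_path_length(validate_connectivity(a, "structural"))
  expect_equal(sp[1, 5], 4)
  # weighted triangle: direct edge cost 10 loses to the two-step route
  wt <- fx$wtri$sc
  sp1 <- shortest_path_length(wt, gamma = 1)
  expect_equal(sp1[1, 3], 2)
  sp125 <- shortest_path_length(wt, gamma = 0.125)
  expect_equal(sp125[1, 3], 0.1^(-0.125), tolerance = 1e-12)
  # igraph oracle on a random weighted graph
  g <- unclass(random_graph(15, seed = 21))
  for (gam in c(0.5, 2)) {
    cost <- ifelse(g > 0, g^(-gam), 0)
    ig <- igraph::graph_from_adjacency_matrix(cost, mode = "undirected",
                                              weighted = TRUE)
    sp <- unclass(shortest_path_length(g, gam))
    attr(sp, "pred") <- NULL
    expect_equal(sp, unname(igraph::distances(ig)), tolerance = 1e-10)
  }
})

test_that("raising a weight never lengthens any shortest path", {
  g <- unclass(random_graph(12, seed = 31))
  base <- unclass(shortest_path_length(g, gamma = 1))
  set.seed(32)
  for (rep in 1:10) {
    edges <- which(upper.tri(g) & g > 0)
    e <- sample(edges, 1)
    g2 <- g
    g2[e] <- g2[e] * runif(1, 1.1, 3)
    g2[lower.tri(g2)] <- t(g2)[lower.tri(g2)]
    after <- unclass(shortest_path_length(g2, gamma = 1))
    expect_true(all(after <= base + 1e-12))
  }
})

test_that("path transitivity averages the matching index along paths", {
  # complete binary graph: every shortest path is direct, so PT = M
  a <- matrix(1, 4, 4); diag(a) <- 0
  k4 <- validate_connectivity(a, "structural")
  expect_equal(unclass(path_transitivity(k4)),
               unclass(matching_index(k4, "binary")), tolerance = 1e-12)
  # path graph: endpoint PT equals the brute-force mean over path node pairs
  a5 <- matrix(0, 5, 5)
  for (i in 1:4) a5[i, i + 1] <- a5[i + 1, i] <- 1
  p5 <- validate_connectivity(a5, "structural")
  m5 <- unclass(matching_index(p5, "binary"))
  pt5 <- path_transitivity(p5)
  pairs <- combn(1:5, 2)
  expect_equal(pt5[1, 5], mean(m5[t(pairs)]), tolerance = 1e-12)
  # nodes sharing no neighbors along the path score 0
  expect_equal(path_transitivity(fx$edge2$sc)[1, 2], 0)
})

test_that("cosine similarity excludes the pair and matches hand values", {
  cs <- cosine_similarity(fx$star5$sc, "binary")
  expect_equal(cs[2, 3], 1)              # identical external neighborhoods
  cp <- cosine_similarity(fx$path3$sc, "binary")
  expect_equal(cp[1, 2], 0)              # orthogonal after exclusion
  # rows [1,2] and [2,1] after exclusion: similarity 4/5
  a <- matrix(0, 4, 4)
  a[1, 3] <- 1; a[1, 4] <- 2
  a[2, 3] <- 2; a[2, 4] <- 1
  a <- a + t(a)
  cw <- cosine_similarity(validate_connectivity(a, "functional"), "weighted")
  expect_equal(cw[1, 2], 4 / 5, tolerance = 1e-12)
})

test_that("search information counts bits along unique shortest paths", {
  # 3-node path: forced first hop, then a 1/2 split = 1 bit
  expect_equal(search_information(fx$path3$sc)[1, 3], 1, tolerance = 1e-12)
  # triangle: direct one-hop path from a degree-2 node = 1 bit
  expect_equal(search_information(fx$k3$sc)[1, 2], 1, tolerance = 1e-12)
  # star: leaf -> hub is forced (0 bits), hub -> leaf is 2 bits; mean 1
  st <- search_information(fx$star5$sc)
  expect_equal(st[1, 2], 1, tolerance = 1e-12)
  expect_equal(st[2, 3], (2 + 2) / 2, tolerance = 1e-12)  # leaf-hub-leaf both ways
  # vertex-transitive ring: symmetric up to numerical noise
  a <- matrix(0, 6, 6)
  for (i in 1:6) { j <- i %% 6 + 1; a[i, j] <- a[j, i] <- 1 }
  ring <- validate_connectivity(a, "structural")
  si <- search_information(ring)
  expect_equal(unclass(si), t(unclass(si)), tolerance = 1e-12)
  # brute-force oracle on a weighted fixture with unique shortest paths
  wt <- unclass(fx$wtri$sc)
  siw <- search_information(wt, gamma = 1)
  p <- wt / rowSums(wt)
  # path 1->3 under gamma=1 goes via 2 (hand-derived above)
  expect_equal(siw[1, 3],
               (-log2(p[1, 2] * p[2, 3]) - log2(p[3, 2] * p[2, 1])) / 2,
               tolerance = 1e-12)
})

test_that("mean first passage time matches cycle formula and Monte Carlo", {
  expect_equal(mean_first_passage_time(fx$edge2$sc, zscore_columns = FALSE)[1, 2], 1,
               tolerance = 1e-10)
  raw4 <- mean_first_passage_time(fx$cycle4$sc, zscore_columns = FALSE)
  expect_equal(raw4[1, 2], 3, tolerance = 1e-10)  # j(N-j) = 1*3
  expect_equal(raw4[1, 3], 4, tolerance = 1e-10)  # 2*2
  # z-scored columns have mean 0 and unit sd over off-diagonal entries
  g <- fx$geo10$sc
  raw <- mean_first_passage_time(g, zscore_columns = FALSE)
  n <- nrow(raw)
  for (j in c(1, 5, 10)) {
    off <- raw[-j, j]
    z <- (off - mean(off)) / sd(off)
    expect_equal(mean(z), 0, tolerance = 1e-10)
    expect_equal(sd(z), 1, tolerance = 1e-10)
  }
  # Monte Carlo oracle on the weighted triangle (3 standard errors)
  wt <- unclass(fx$wtri$sc)
  mc <- mc_mfpt(wt, n_walks = 20000, seed = 9)
  an <- mean_first_passage_time(wt, zscore_columns = FALSE)
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    expect_lt(abs(an[i, j] - mc$est[i, j]), 3 * mc$se[i, j])
  }
})

test_that("Euclidean distances are metric", {
  geo <- parcel_geometry(rbind(c(0, 0, 1), c(3, 4, 1)))
  expect_equal(euclidean_matrix(geo)[1, 2], 5)
  d <- euclidean_matrix(fx$geo10$geometry)
  for (i in 1:10) for (j in 1:10) for (k in 1:10) {
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
})

test_that("the battery has 40 predictors in 10 classes with clean matrices", {
  b <- build_battery(fx$geo10$sc, fx$geo10$geometry)
  expect_length(b$matrices, 40)
  expect_identical(b$labels, names(b$matrices))
  counts <- table(unname(b$classes))
  expect_length(counts, 10)
  expect_equal(as.numeric(counts[c("flow graph", "navigation", "communicability",
                                   "path transitivity", "matching index",
                                   "path length", "cosine similarity",
                                   "search information", "MFPT", "Euclidean")]),
               c(8, 2, 2, 7, 2, 7, 2, 7, 2, 1))
  for (lb in b$labels) {
    m <- b$matrices[[lb]]
    expect_equal(diag(m), rep(0, nrow(m)), info = lb)
    fin <- is.finite(m)
    expect_equal(m[fin & t(fin)], t(m)[fin & t(fin)], tolerance = 1e-9,
                 info = lb)
    if (!startsWith(lb, "nav")) expect_true(all(is.finite(m)), info = lb)
  }
  # determinism: a second build is bit-identical
  b2 <- build_battery(fx$geo10$sc, fx$geo10$geometry)
  expect_identical(b$matrices, b2$matrices)
  # compute_predictor reproduces every battery member from its label
  for (lb in c("fg-wei-2.5", "si-wei-0.25", "pt-bin", "mfpt-wei", "euc")) {
    expect_equal(compute_predictor(fx$geo10$sc, fx$geo10$geometry, lb),
                 b$matrices[[lb]], tolerance = 1e-12, info = lb)
  }
})
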