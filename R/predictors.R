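#' @title Communication-model predictor battery
#' @description Ten classes of predictor matrices derived from a sparse
#' structural connectivity matrix: flow graphs, greedy navigation,
#' communicability, path transitivity, matching index, shortest path length,
#' cosine similarity, search information, mean first passage time, and
#' Euclidean distance. Parameterized classes are evaluated over a grid of
#' Markov times (flow graphs) or weight-to-cost exponents (path-based
#' classes), for 40 predictors in total.
#' @name predictor-battery
NULL

binarize <- function(m) {
  b <- (unclass(m) > 0) * 1
  diag(b) <- 0
  b
}

# exp(M) for symmetric M via eigendecomposition
expm_sym <- function(m, scale = 1) {
  e <- eigen(m, symmetric = TRUE)
  v <- e$vectors
  out <- v %*% (exp(scale * e$values) * t(v))
  (out + t(out)) / 2
}

#' Flow graph at Markov time t
#'
#' Embeds the dynamics of a continuous-time random walk into edge weights:
#' with node strengths `s_i = sum_j A_ij`, `D = diag(s)` and random-walk
#' Laplacian `L = I - A D^-1`, the flow graph is `A'(t) = exp(-t L) D`.
#' Computed through the symmetric normalized Laplacian so the output is
#' exactly symmetric; its column sums equal the strengths `s_j` at every t
#' (probability mass is conserved). The diagonal (walkers that have not left)
#' is retained here; [build_battery()] zeroes it for regression use.
#'
#' @param sc structural connectivity matrix.
#' @param t Markov time (nonnegative). The battery uses `c(1, 2.5, 5, 10)`.
#' @param variant `"binary"` binarizes the matrix first; `"weighted"` uses
#'   the weights as given.
#' @return N x N symmetric flow-graph matrix.
#' @export
flow_graph <- function(sc, t, variant = c("weighted", "binary")) {
  variant <- match.arg(variant)
  a <- as_square_matrix(sc)
  if (variant == "binary") a <- binarize(a)
  s <- rowSums(a)
  if (any(s <= 0)) stop("flow graph undefined for isolated nodes (zero strength)")
  if (t < 0) stop("Markov time must be nonnegative")
  # exp(-tL) = D^{1/2} exp(-t L_sym) D^{-1/2} with L_sym = I - D^{-1/2} A D^{-1/2},
  # hence A'(t) = exp(-tL) D = D^{1/2} exp(-t L_sym) D^{1/2}, symmetric.
  ds <- sqrt(s)
  lsym <- diag(nrow(a)) - a / outer(ds, ds)
  e <- expm_sym(lsym, scale = -t)
  out <- outer(ds, ds) * e
  (out + t(out)) / 2
}

#' Greedy navigation
#'
#' For each ordered pair (s, t), repeatedly hop to the connected neighbor
#' closest to the target in Euclidean space. Returns both the number of hops
#' (`nav_num`) and the total traversed Euclidean length (`nav_ms`). Routes
#' that revisit a node or exceed N hops fail and are imputed with `Inf` in
#' both outputs. The two directed values for each pair are averaged (with
#' `Inf` dominating) so the outputs are symmetric.
#'
#' @param sc structural connectivity matrix (connected).
#' @param geometry [parcel_geometry()] supplying centroids.
#' @return list with elements `nav_num` and `nav_ms`, both N x N.
#' @export
navigation <- function(sc, geometry) {
  a <- as_square_matrix(sc)
  metric <- euclidean_matrix(geometry)
  res <- cpp_navigate(a, metric)
  list(nav_num = symmetrize_mean(res$hops),
       nav_ms = symmetrize_mean(res$length))
}

symmetrize_mean <- function(m) (m + t(m)) / 2

#' Communicability
#'
#' Weighted sum of walks of all lengths between node pairs. The binary
#' variant is `G = exp(A)` of the binarized adjacency; the weighted variant
#' first normalizes the adjacency as `D^-1/2 A D^-1/2` (D the diagonal
#' strength matrix) before exponentiating.
#'
#' @inheritParams flow_graph
#' @return N x N symmetric communicability matrix.
#' @export
communicability <- function(sc, variant = c("weighted", "binary")) {
  variant <- match.arg(variant)
  a <- as_square_matrix(sc)
  if (variant == "binary") {
    expm_sym(binarize(a))
  } else {
    s <- rowSums(a)
    if (any(s <= 0)) stop("weighted communicability undefined for isolated nodes")
    ds <- sqrt(s)
    expm_sym(a / outer(ds, ds))
  }
}

#' Matching index
#'
#' Overlap between the connectivity profiles of node pairs. The binary form
#' is the Jaccard-style ratio `|Γ_i\\j ∩ Γ_j\\i| / |Γ_i\\j ∪ Γ_j\\i|` where
#' `Γ_i\\j` is the neighbor set of i excluding j. The weighted form follows
#' the common toolbox convention
#' `Σ_{k∈∩}(A_ik + A_jk) / Σ_{k∈∪}(A_ik + A_jk)` with k ranging over
#' neighbors other than i and j. Pairs with an empty union score 0.
#'
#' @inheritParams flow_graph
#' @return N x N symmetric matrix with values in `[0, 1]`.
#' @export
matching_index <- function(sc, variant = c("weighted", "binary")) {
  variant <- match.arg(variant)
  a <- as_square_matrix(sc)
  b <- binarize(a)
  if (variant == "binary") {
    common <- b %*% b          # zero diagonal of b excludes k in {i, j}
    deg <- rowSums(b)
    union <- outer(deg, deg, "+") - 2 * b - common
    m <- ifelse(union > 0, common / pmax(union, .Machine$double.eps), 0)
  } else {
    num <- a %*% b + b %*% a   # sum over shared neighbors of A_ik + A_jk
    s <- rowSums(a)
    den <- outer(s, s, "+") - 2 * a
    m <- ifelse(den > 0, num / pmax(den, .Machine$double.eps), 0)
  }
  m <- pmin(pmax(m, 0), 1)
  diag(m) <- 0
  symmetrize_mean(m)
}

#' Shortest path length
#'
#' All-pairs minimal path cost by Dijkstra's algorithm with deterministic
#' lowest-index tie-breaking. With `gamma = NULL` the graph is binarized and
#' unit costs give hop counts; otherwise costs come from the weight-to-cost
#' transform `C_ij = A_ij^-gamma`. The predecessor trees are attached as
#' attribute `"pred"` for reuse by search information and path transitivity.
#'
#' @param sc structural connectivity matrix.
#' @param gamma `NULL` for the binary variant, or a positive exponent.
#' @return N x N matrix of path costs with attribute `"pred"`.
#' @export
shortest_path_length <- function(sc, gamma = NULL) {
  cost <- if (is.null(gamma)) {
    cb <- ifelse(binarize(sc) > 0, 1, Inf)
    diag(cb) <- 0
    cb
  } else {
    weight_to_cost(sc, gamma)
  }
  res <- cpp_dijkstra_all(unclass(cost))
  out <- res$dist
  attr(out, "pred") <- res$pred
  out
}

#' Path transitivity
#'
#' For each pair (s, t), the mean matching index over all pairs of nodes on
#' the retained shortest path (endpoints included): with path node sequence
#' of length k, `PT_st = 2/(k(k-1)) * Σ_{i<j on path} M_ij`. A direct edge
#' (k = 2) reduces to `M_st`. The binary variant pairs the binary matching
#' index with binary shortest paths; weighted variants pair the weighted
#' matching index with paths under the corresponding weight-to-cost exponent.
#'
#' @inheritParams shortest_path_length
#' @return N x N symmetric matrix with values in `[0, 1]`.
#' @export
path_transitivity <- function(sc, gamma = NULL) {
  variant <- if (is.null(gamma)) "binary" else "weighted"
  m <- matching_index(sc, variant)
  sp <- shortest_path_length(sc, gamma)
  cpp_path_transitivity(attr(sp, "pred"), unclass(m))
}

#' Cosine similarity of connectivity profiles
#'
#' Cosine of the angle between the connectivity profiles (matrix rows) of
#' each node pair, after deleting entries i and j from both rows. Zero-norm
#' profiles score 0.
#'
#' @inheritParams flow_graph
#' @return N x N symmetric matrix.
#' @export
cosine_similarity <- function(sc, variant = c("weighted", "binary")) {
  variant <- match.arg(variant)
  a <- as_square_matrix(sc)
  if (variant == "binary") a <- binarize(a)
  # With zero diagonal, deleting entries i and j leaves dot product (A^2)_ij
  # and squared norms rowSums(A^2) - A_ij^2.
  dot <- a %*% a
  q <- rowSums(a^2)
  ni <- outer(q, rep(1, length(q))) - a^2
  nj <- t(ni)
  den <- sqrt(pmax(ni, 0) * pmax(nj, 0))
  s <- ifelse(den > 0, dot / pmax(den, .Machine$double.eps), 0)
  diag(s) <- 0
  symmetrize_mean(s)
}

#' Search information
#'
#' The information (in bits) a random walker needs to follow the retained
#' shortest path from s to t: `SI(s,t) = -log2 P(π_s→t)` where the path
#' probability multiplies the one-step transition probabilities
#' `p_ij = A_ij / s_i` along the path. Values are nonnegative (the sign is
#' chosen so that rarer paths cost more bits). Transition probabilities
#' always use the graph the paths were computed on: the binary variant uses
#' binary weights and binary shortest paths, the weighted variants use raw
#' weights with paths under the corresponding weight-to-cost exponent. The
#' directed values are averaged so the output is symmetric.
#'
#' @inheritParams shortest_path_length
#' @return N x N symmetric matrix of path information (bits).
#' @export
search_information <- function(sc, gamma = NULL) {
  a <- as_square_matrix(sc)
  if (is.null(gamma)) a <- binarize(a)
  s <- rowSums(a)
  if (any(s <= 0)) stop("search information undefined for isolated nodes")
  prob <- a / s
  sp <- shortest_path_length(sc, gamma)
  si <- cpp_search_information(attr(sp, "pred"), prob)
  symmetrize_mean(si)
}

#' Mean first passage time
#'
#' Expected number of steps for a random walk started at i to first reach j.
#' With transition matrix `P = D^-1 A`, stationary distribution
#' `π_j = s_j / Σ s`, and fundamental matrix `Z = (I - P + 1 π')^-1`, the raw
#' values are `MFPT_ij = (Z_jj - Z_ij) / π_j`. Columns are then expressed as
#' z-scores over their off-diagonal entries to remove nodal (column) biases,
#' and the result is symmetrized by the element-wise mean.
#'
#' @inheritParams flow_graph
#' @param zscore_columns set `FALSE` to return the raw asymmetric
#'   first-passage times (used by oracle tests).
#' @return N x N matrix (symmetric when `zscore_columns = TRUE`).
#' @export
mean_first_passage_time <- function(sc, variant = c("weighted", "binary"),
                                    zscore_columns = TRUE) {
  variant <- match.arg(variant)
  a <- as_square_matrix(sc)
  if (variant == "binary") a <- binarize(a)
  s <- rowSums(a)
  if (any(s <= 0)) stop("mean first passage time undefined for isolated nodes")
  n <- nrow(a)
  p <- a / s
  pi_st <- s / sum(s)
  z <- solve(diag(n) - p + matrix(pi_st, n, n, byrow = TRUE))
  mfpt <- (matrix(diag(z), n, n, byrow = TRUE) - z) /
    matrix(pi_st, n, n, byrow = TRUE)
  diag(mfpt) <- 0
  if (!zscore_columns) return(mfpt)
  out <- mfpt
  for (j in seq_len(n)) {
    off <- mfpt[-j, j]
    out[-j, j] <- (off - mean(off)) / sd(off)
    out[j, j] <- 0
  }
  symmetrize_mean(out)
}

#' Euclidean distance matrix
#'
#' Pairwise Euclidean distance between parcel centroids.
#'
#' @param geometry [parcel_geometry()] object.
#' @return N x N symmetric distance matrix with zero diagonal.
#' @export
euclidean_matrix <- function(geometry) {
  d <- as.matrix(stats::dist(geometry$centroids))
  dimnames(d) <- NULL
  d
}

#' Build the 40-predictor battery
#'
#' Assembles the full predictor stack from one structural matrix plus parcel
#' geometry: flow graphs (binary and weighted at each Markov time), the two
#' navigation measures, binary and weighted communicability, path
#' transitivity (binary plus one per weight-to-cost exponent), binary and
#' weighted matching index, path length (binary plus one per exponent),
#' binary and weighted cosine similarity, search information (binary plus one
#' per exponent), binary and weighted mean first passage time, and Euclidean
#' distance. With the default grids this is exactly 40 predictors in 10
#' classes. All matrices are symmetric with zero diagonal; only the
#' navigation matrices may contain non-finite (`Inf`) entries.
#'
#' @param sc structural connectivity matrix (validated).
#' @param geometry [parcel_geometry()] object.
#' @param gammas weight-to-cost exponents for path-based classes.
#' @param markov_times Markov times for the flow graphs.
#' @return object of class `"predictor_stack"`: list with `matrices` (named
#'   list of N x N matrices), `labels`, and `classes` (label -> class map).
#' @export
build_battery <- function(sc, geometry,
                          gammas = c(0.125, 0.25, 0.5, 1, 2, 4),
                          markov_times = c(1, 2.5, 5, 10)) {
  a <- as_square_matrix(sc)
  mats <- list()
  classes <- character()
  add <- function(label, m, cls) {
    m <- unclass(m)
    attr(m, "pred") <- NULL
    diag(m) <- 0
    mats[[label]] <<- m
    classes[[label]] <<- cls
  }
  for (t in markov_times) add(sprintf("fg-bin-%g", t), flow_graph(a, t, "binary"), "flow graph")
  for (t in markov_times) add(sprintf("fg-wei-%g", t), flow_graph(a, t, "weighted"), "flow graph")
  nav <- navigation(a, geometry)
  add("nav-num", nav$nav_num, "navigation")
  add("nav-ms", nav$nav_ms, "navigation")
  add("comm-bin", communicability(a, "binary"), "communicability")
  add("comm-wei", communicability(a, "weighted"), "communicability")
  # binary path machinery is shared across pt/pl/si, as is each gamma's
  mbin <- matching_index(a, "binary")
  spb <- shortest_path_length(a, NULL)
  add("pt-bin", cpp_path_transitivity(attr(spb, "pred"), unclass(mbin)), "path transitivity")
  mwei <- matching_index(a, "weighted")
  sp_g <- lapply(gammas, function(g) shortest_path_length(a, g))
  for (i in seq_along(gammas)) {
    add(sprintf("pt-wei-%g", gammas[i]),
        cpp_path_transitivity(attr(sp_g[[i]], "pred"), unclass(mwei)),
        "path transitivity")
  }
  add("mi-bin", mbin, "matching index")
  add("mi-wei", mwei, "matching index")
  add("pl-bin", spb, "path length")
  for (i in seq_along(gammas)) {
    add(sprintf("pl-wei-%g", gammas[i]), sp_g[[i]], "path length")
  }
  add("cos-bin", cosine_similarity(a, "binary"), "cosine similarity")
  add("cos-wei", cosine_similarity(a, "weighted"), "cosine similarity")
  bprob <- binarize(a) / rowSums(binarize(a))
  add("si-bin", symmetrize_mean(cpp_search_information(attr(spb, "pred"), bprob)),
      "search information")
  wprob <- a / rowSums(a)
  for (i in seq_along(gammas)) {
    add(sprintf("si-wei-%g", gammas[i]),
        symmetrize_mean(cpp_search_information(attr(sp_g[[i]], "pred"), wprob)),
        "search information")
  }
  add("mfpt-bin", mean_first_passage_time(a, "binary"), "MFPT")
  add("mfpt-wei", mean_first_passage_time(a, "weighted"), "MFPT")
  add("euc", euclidean_matrix(geometry), "Euclidean")
  structure(list(matrices = mats, labels = names(mats), classes = classes),
            class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf("predictor stack: %d predictors, %d classes, %d nodes\n",
              length(x$matrices), length(unique(x$classes)),
              nrow(x$matrices[[1]])))
  invisible(x)
}
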