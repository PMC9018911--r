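#' @title Structure-function coupling regression
#' @description Ordinary least squares machinery linking functional
#' connectivity to communication-model predictors: global (edge-wise) fits,
#' hop-stratified fits, regional fits, best-predictor bookkeeping, greedy
#' two-predictor models, all-predictor and principal-component models, and
#' the direct structural-weight comparison. All reported values are
#' in-sample R-squared.
#' @name coupling-regression
NULL

MIN_FIT_SAMPLES <- 10L

#' Simple linear fit
#'
#' OLS of y on a single predictor with intercept. Pairs where the predictor
#' is non-finite are dropped (navigation imputes failed routes with `Inf`);
#' the number of samples actually used is reported.
#'
#' @param y numeric response vector.
#' @param x numeric predictor vector.
#' @return list with `r2`, `intercept`, `slope`, `n_used`.
#' @export
simple_fit <- function(y, x) {
  keep <- is.finite(x) & is.finite(y)
  n <- sum(keep)
  if (n < MIN_FIT_SAMPLES) {
    stop(sprintf("fewer than %d finite paired samples", MIN_FIT_SAMPLES))
  }
  y <- y[keep]; x <- x[keep]
  if (sd(y) == 0) stop("zero-variance response")
  if (sd(x) == 0) stop("zero-variance predictor")
  slope <- cov(x, y) / var(x)
  intercept <- mean(y) - slope * mean(x)
  r <- cor(x, y)
  list(r2 = r * r, intercept = intercept, slope = slope, n_used = n)
}

#' Adjusted R-squared
#'
#' `R2_adj = 1 - (1 - R2)(n - 1)/(n - p - 1)` where `p` counts model
#' parameters including the intercept (p = 2 for the one-predictor model,
#' p = 3 for the two-predictor model).
#'
#' @param r2 unadjusted R-squared.
#' @param n number of samples used in the fit.
#' @param p number of model parameters including the intercept.
#' @return adjusted R-squared.
#' @export
adjusted_r2 <- function(r2, n, p) {
  if (any(n <= p + 1)) stop("adjusted R2 requires n > p + 1")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

# r2 of y ~ x with pairwise-finite filtering; NA if infeasible
r2_or_na <- function(y, x) {
  keep <- is.finite(x) & is.finite(y)
  if (sum(keep) < MIN_FIT_SAMPLES) return(NA_real_)
  ys <- y[keep]; xs <- x[keep]
  if (sd(ys) == 0 || sd(xs) == 0) return(NA_real_)
  cor(xs, ys)^2
}

upper_tri_vec <- function(m) m[upper.tri(m)]

#' Global structure-function coupling
#'
#' For each predictor, OLS of the vectorized upper triangle of FC on the
#' matching entries of the predictor matrix.
#'
#' @param fc functional connectivity matrix.
#' @param stack [build_battery()] predictor stack.
#' @return named vector of R-squared values, one per predictor.
#' @export
global_coupling <- function(fc, stack) {
  y <- upper_tri_vec(as_square_matrix(fc))
  vapply(stack$matrices, function(p) r2_or_na(y, upper_tri_vec(p)), numeric(1))
}

#' Hop-stratified coupling
#'
#' Stratifies node pairs by their binary shortest-path hop count and fits a
#' separate edge-wise OLS per stratum and predictor. The hop-1 stratum is
#' the direct-connection subset. Strata with fewer than 10 pairs are NA.
#'
#' @inheritParams global_coupling
#' @param sc structural connectivity matrix used to define hop counts.
#' @param max_hops hop classes beyond this are pooled into the last class.
#' @return matrix of R-squared values, hop class x predictor.
#' @export
hop_decomposition <- function(fc, stack, sc, max_hops = 5L) {
  hops <- shortest_path_length(sc, gamma = NULL)
  h <- upper_tri_vec(unclass(hops))
  h <- pmin(h, max_hops)
  y <- upper_tri_vec(as_square_matrix(fc))
  classes <- sort(unique(h[is.finite(h)]))
  out <- matrix(NA_real_, length(classes), length(stack$labels),
                dimnames = list(paste0("hop", classes), stack$labels))
  for (ci in seq_along(classes)) {
    sel <- h == classes[ci]
    for (p in seq_along(stack$matrices)) {
      out[ci, p] <- r2_or_na(y[sel], upper_tri_vec(stack$matrices[[p]])[sel])
    }
  }
  out
}

# row-wise r2 between two matrices, excluding the diagonal entry of each row;
# fully vectorized when the predictor has no non-finite entries
rowwise_r2 <- function(fc, pm) {
  n <- nrow(fc)
  if (all(is.finite(pm))) {
    k <- n - 1
    sx <- rowSums(pm); sy <- rowSums(fc)
    sxx <- rowSums(pm^2); syy <- rowSums(fc^2); sxy <- rowSums(pm * fc)
    vx <- sxx - sx^2 / k
    vy <- syy - sy^2 / k
    cv <- sxy - sx * sy / k
    r2 <- ifelse(vx > 1e-300 & vy > 1e-300, cv^2 / (vx * vy), NA_real_)
    list(r2 = r2, n_used = rep(k, n))
  } else {
    r2 <- numeric(n); nu <- integer(n)
    for (i in seq_len(n)) {
      y <- fc[i, -i]; x <- pm[i, -i]
      r2[i] <- r2_or_na(y, x)
      nu[i] <- sum(is.finite(x) & is.finite(y))
    }
    list(r2 = r2, n_used = nu)
  }
}

#' Regional structure-function coupling
#'
#' For each region i and each predictor, OLS of row i of FC (self-connection
#' excluded) on row i of the predictor matrix, dropping pairs where the
#' predictor is non-finite.
#'
#' @inheritParams global_coupling
#' @return N x P matrix of R-squared values with attribute `n_used`.
#' @export
regional_coupling <- function(fc, stack) {
  fcm <- as_square_matrix(fc)
  res <- lapply(stack$matrices, function(p) rowwise_r2(fcm, p))
  r2 <- do.call(cbind, lapply(res, `[[`, "r2"))
  nu <- do.call(cbind, lapply(res, `[[`, "n_used"))
  colnames(r2) <- colnames(nu) <- stack$labels
  attr(r2, "n_used") <- nu
  r2
}

#' Best predictor per region
#'
#' Argmax over predictors of the regional R-squared, with exact ties broken
#' by battery order (the earlier label wins).
#'
#' @param r2 region x predictor matrix of R-squared values.
#' @return data.frame with `label` and `r2` per region.
#' @export
best_predictor <- function(r2) {
  labs <- colnames(r2)
  idx <- apply(r2, 1, function(row) {
    if (all(is.na(row))) NA_integer_ else which.max(row)
  })
  val <- rep(NA_real_, nrow(r2))
  lab <- rep(NA_character_, nrow(r2))
  ok <- !is.na(idx)
  val[ok] <- r2[cbind(which(ok), idx[ok])]
  lab[ok] <- labs[idx[ok]]
  data.frame(label = lab, r2 = val, stringsAsFactors = FALSE)
}

# two-predictor OLS r2 by closed-form normal equations on the jointly finite
# sample; falls back to the better single predictor if collinear
r2_pair <- function(y, x1, x2) {
  keep <- is.finite(y) & is.finite(x1) & is.finite(x2)
  if (sum(keep) < MIN_FIT_SAMPLES) return(NA_real_)
  y <- y[keep]; x1 <- x1[keep]; x2 <- x2[keep]
  yc <- y - mean(y); a <- x1 - mean(x1); b <- x2 - mean(x2)
  saa <- sum(a * a); sbb <- sum(b * b); sab <- sum(a * b)
  say <- sum(a * yc); sby <- sum(b * yc); syy <- sum(yc * yc)
  if (syy <= 0) return(NA_real_)
  det <- saa * sbb - sab * sab
  if (det <= 1e-12 * max(saa * sbb, 1e-300)) {
    r1 <- if (saa > 0) say^2 / (saa * syy) else NA_real_
    r2 <- if (sbb > 0) sby^2 / (sbb * syy) else NA_real_
    return(max(r1, r2, na.rm = TRUE))
  }
  b1 <- (sbb * say - sab * sby) / det
  b2 <- (saa * sby - sab * say) / det
  min(max((b1 * say + b2 * sby) / syy, 0), 1)
}

#' Greedy two-predictor selection
#'
#' Finds the single best predictor of a regional FC profile, then the second
#' predictor that maximizes the two-predictor OLS R-squared, and reports the
#' improvement as the difference in adjusted R-squared between the
#' two-predictor (p = 3) and one-predictor (p = 2) models. The improvement
#' may be negative and is reported as computed.
#'
#' @param y regional FC profile (self-connection already excluded).
#' @param x matrix of the matching predictor-row values, one column per
#'   predictor.
#' @param labels predictor labels (defaults to `colnames(x)`).
#' @return list with `best`, `second`, `r2_1`, `r2_2`, `delta_r2_adj`,
#'   `n_used`.
#' @export
greedy_pair_fit <- function(y, x, labels = colnames(x)) {
  p <- ncol(x)
  singles <- vapply(seq_len(p), function(j) r2_or_na(y, x[, j]), numeric(1))
  if (all(is.na(singles))) stop("no feasible single-predictor fit")
  best <- which.max(singles)
  pair_r2 <- rep(NA_real_, p)
  for (j in seq_len(p)) {
    if (j == best) next
    pair_r2[j] <- r2_pair(y, x[, best], x[, j])
  }
  second <- which.max(pair_r2)
  keep <- is.finite(y) & is.finite(x[, best]) & is.finite(x[, second])
  n <- sum(keep)
  r2_1 <- singles[best]
  r2_2 <- pair_r2[second]
  list(best = labels[best], second = labels[second],
       r2_1 = r2_1, r2_2 = r2_2,
       delta_r2_adj = adjusted_r2(r2_2, n, 3) - adjusted_r2(r2_1, n, 2),
       n_used = n)
}

#' Pair-count matrix
#'
#' Counts how often each unordered pair of predictors was selected together
#' by the greedy two-predictor analysis across subjects and regions.
#'
#' @param best character vector of first-selected labels.
#' @param second character vector of second-selected labels, aligned with
#'   `best`.
#' @param labels full battery label set fixing the matrix order.
#' @return symmetric P x P integer count matrix with zero diagonal.
#' @export
pair_counts <- function(best, second, labels) {
  p <- length(labels)
  counts <- matrix(0L, p, p, dimnames = list(labels, labels))
  i <- match(best, labels)
  j <- match(second, labels)
  ok <- !is.na(i) & !is.na(j) & i != j
  for (k in which(ok)) {
    counts[i[k], j[k]] <- counts[i[k], j[k]] + 1L
    counts[j[k], i[k]] <- counts[j[k], i[k]] + 1L
  }
  counts
}

# minimum-norm least squares via SVD; returns r2
lsq_r2 <- function(y, x) {
  x <- cbind(1, x)
  sv <- svd(x)
  tol <- max(dim(x)) * .Machine$double.eps * max(sv$d)
  pos <- sv$d > tol
  coef <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
  res <- y - x %*% coef
  1 - sum(res^2) / sum((y - mean(y))^2)
}

#' Full multi-predictor model
#'
#' OLS of a regional FC profile on all predictors at once. Predictors with
#' non-finite entries on this row are dropped (and named in attribute
#' `"dropped"`); rank-deficient designs are solved by minimum-norm least
#' squares. With ~40 correlated predictors and ~N samples this model
#' overfits by construction, which is the point of the comparison.
#'
#' @inheritParams greedy_pair_fit
#' @return R-squared with attribute `dropped`.
#' @export
full_model_fit <- function(y, x) {
  keep_rows <- is.finite(y)
  finite_cols <- colSums(!is.finite(x[keep_rows, , drop = FALSE])) == 0
  if (sum(keep_rows) <= sum(finite_cols) + 1) {
    stop("full model requires more samples than predictors")
  }
  r2 <- lsq_r2(y[keep_rows], x[keep_rows, finite_cols, drop = FALSE])
  structure(r2, dropped = colnames(x)[!finite_cols])
}

#' Principal-component predictor model
#'
#' Replaces the predictor columns by their top-k principal components
#' (columns standardized first) before the OLS fit, addressing collinearity
#' among predictors.
#'
#' @inheritParams greedy_pair_fit
#' @param k number of components to retain.
#' @return R-squared.
#' @export
pca_predictor_fit <- function(y, x, k) {
  keep_rows <- is.finite(y)
  finite_cols <- colSums(!is.finite(x[keep_rows, , drop = FALSE])) == 0
  xs <- scale(x[keep_rows, finite_cols, drop = FALSE])
  xs <- xs[, apply(xs, 2, function(cl) all(is.finite(cl))), drop = FALSE]
  if (k > ncol(xs)) stop("k exceeds the number of usable predictors")
  sv <- svd(xs)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  lsq_r2(y[keep_rows], scores)
}

#' Direct structural-weight fit
#'
#' For each region, restricts to the node pairs where a structural
#' connection exists and fits FC weights on SC weights. Regions with fewer
#' than 10 structural connections are NA.
#'
#' @param fc functional connectivity matrix.
#' @param sc structural connectivity matrix.
#' @return vector of R-squared values, one per region.
#' @export
sc_direct_fit <- function(fc, sc) {
  fcm <- as_square_matrix(fc); scm <- as_square_matrix(sc)
  n <- nrow(fcm)
  vapply(seq_len(n), function(i) {
    mask <- scm[i, -i] > 0
    if (sum(mask) < MIN_FIT_SAMPLES) return(NA_real_)
    r2_or_na(fcm[i, -i][mask], scm[i, -i][mask])
  }, numeric(1))
}

#' Optimal-predictor frequency
#'
#' For each region, the fraction of subjects for which each predictor was
#' the best regional predictor. Rows sum to 1.
#'
#' @param best_labels subjects x regions character matrix of best labels.
#' @param labels battery label set fixing the column order.
#' @return region x P frequency matrix.
#' @export
optimal_frequency <- function(best_labels, labels) {
  nr <- ncol(best_labels)
  h <- matrix(0, nr, length(labels), dimnames = list(NULL, labels))
  for (i in seq_len(nr)) {
    tab <- table(factor(best_labels[, i], levels = labels))
    tot <- sum(tab)
    if (tot > 0) h[i, ] <- as.numeric(tab) / tot
  }
  h
}

#' Two-dimensional predictor embedding
#'
#' Correlates the regional R-squared profiles of every pair of predictors,
#' keeps each predictor's k largest neighbors (union-symmetrized), and takes
#' the first two principal components of the thresholded matrix without
#' centering or scaling the columns.
#'
#' @param regional_r2 region x predictor matrix (typically averaged over
#'   subjects).
#' @param k number of nearest neighbors retained per predictor.
#' @return P x 2 matrix of embedding coordinates, with the thresholded
#'   similarity matrix as attribute `"graph"`.
#' @export
predictor_embedding <- function(regional_r2, k = 4) {
  if (ncol(regional_r2) < 5) stop("embedding needs at least 5 predictors")
  cc <- cor(regional_r2, use = "pairwise.complete.obs")
  if (any(!is.finite(cc))) stop("constant regional profile: correlation undefined")
  p <- ncol(cc)
  keep <- matrix(FALSE, p, p)
  for (i in seq_len(p)) {
    ord <- order(cc[i, -i], decreasing = TRUE)
    nb <- seq_len(p)[-i][ord[seq_len(k)]]
    keep[i, nb] <- TRUE
  }
  keep <- keep | t(keep)
  w <- ifelse(keep, cc, 0)
  diag(w) <- 1  # self-similarity retained so duplicate predictors coincide
  sv <- svd(w)
  coords <- sv$u[, 1:2, drop = FALSE] %*% diag(sv$d[1:2], 2)
  rownames(coords) <- colnames(regional_r2)
  colnames(coords) <- c("PC1", "PC2")
  structure(coords, graph = w)
}

#' Per-subject regional fits across a cohort
#'
#' Builds the predictor battery and regional fits for every subject of a
#' cohort, returning the bookkeeping the group-level analyses consume: best
#' label and maximum R-squared per subject and region, the best global fit
#' per subject, and the subject-averaged region x predictor R-squared
#' matrix.
#'
#' @param sc_list list of per-subject structural matrices.
#' @param fc_list list of per-subject functional matrices.
#' @param geometry shared [parcel_geometry()].
#' @param gammas,markov_times battery parameter grids, see
#'   [build_battery()].
#' @return list with `best_labels` (subjects x regions), `max_r2` (subjects
#'   x regions), `global_best` and `global_max` (per subject), `mean_r2`
#'   (regions x predictors), and `labels`.
#' @export
cohort_coupling <- function(sc_list, fc_list, geometry,
                            gammas = c(0.125, 0.25, 0.5, 1, 2, 4),
                            markov_times = c(1, 2.5, 5, 10)) {
  ns <- length(sc_list)
  stopifnot(length(fc_list) == ns)
  mean_r2 <- NULL
  best_labels <- NULL
  max_r2 <- NULL
  global_best <- character(ns)
  global_max <- numeric(ns)
  labels <- NULL
  for (s in seq_len(ns)) {
    stack <- build_battery(sc_list[[s]], geometry,
                           gammas = gammas, markov_times = markov_times)
    if (is.null(labels)) {
      labels <- stack$labels
      n_reg <- nrow(sc_list[[s]])
      best_labels <- matrix(NA_character_, ns, n_reg)
      max_r2 <- matrix(NA_real_, ns, n_reg)
      mean_r2 <- matrix(0, n_reg, length(labels),
                        dimnames = list(NULL, labels))
    }
    r2 <- regional_coupling(fc_list[[s]], stack)
    bp <- best_predictor(r2)
    best_labels[s, ] <- bp$label
    max_r2[s, ] <- bp$r2
    mean_r2 <- mean_r2 + ifelse(is.na(r2), 0, r2)
    gl <- global_coupling(fc_list[[s]], stack)
    global_best[s] <- labels[which.max(gl)]
    global_max[s] <- max(gl, na.rm = TRUE)
  }
  list(best_labels = best_labels, max_r2 = max_r2,
       global_best = global_best, global_max = global_max,
       mean_r2 = mean_r2 / ns, labels = labels)
}
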