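#' Spatially constrained (spin) permutations
#'
#' Generates permutations of parcels that preserve spatial autocorrelation:
#' each permutation applies a uniformly random 3D rotation to the unit-sphere
#' parcel coordinates and then maps each parcel to the nearest rotated parcel
#' by greedy one-to-one assignment in random parcel order (forcing a true
#' permutation).
#'
#' After the greedy pass, pairwise swaps that reduce the total assignment
#' distance are applied to convergence (`refine = TRUE`), bringing the
#' permutation close to the optimal assignment for the drawn rotation; this
#' measurably improves how faithfully spun maps preserve the spatial
#' autocorrelation of the original at coarse parcellations.
#'
#' @param sphere_coords N x 3 unit-norm coordinates (or a
#'   [parcel_geometry()] object).
#' @param n_perm number of permutations (default 1000).
#' @param seed optional RNG seed for reproducibility.
#' @param refine apply 2-swap improvement passes after the greedy assignment
#'   (default TRUE).
#' @return `n_perm` x N integer matrix of class `"spin_set"`; each row is a
#'   permutation of `1:N`.
#' @export
spin_permutations <- function(sphere_coords, n_perm = 1000, seed = NULL,
                              refine = TRUE) {
  if (inherits(sphere_coords, "parcel_geometry")) {
    sphere_coords <- sphere_coords$sphere_coords
  }
  xyz <- as.matrix(sphere_coords)
  n <- nrow(xyz)
  if (any(abs(sqrt(rowSums(xyz^2)) - 1) > 1e-8)) {
    stop("sphere coordinates must have unit norm")
  }
  if (anyDuplicated(round(xyz, 10))) {
    stop("degenerate (duplicate) sphere coordinates")
  }
  if (!is.null(seed)) set.seed(seed)
  perms <- matrix(NA_integer_, n_perm, n)
  for (r in seq_len(n_perm)) {
    rot <- random_rotation()
    rotated <- xyz %*% rot
    # dot product is a monotone proxy for closeness on the unit sphere
    dots <- xyz %*% t(rotated)
    avail <- rep(TRUE, n)
    perm <- integer(n)
    for (i in sample.int(n)) {
      cand <- which(avail)
      j <- cand[which.max(dots[i, cand])]
      perm[i] <- j
      avail[j] <- FALSE
    }
    if (refine) {
      # 2-swap passes toward the optimal assignment for this rotation
      repeat {
        cur <- dots[cbind(seq_len(n), perm)]
        improved <- FALSE
        for (i in seq_len(n - 1)) {
          rest <- (i + 1):n
          gains <- dots[i, perm[rest]] + dots[cbind(rest, perm[i])] -
            cur[i] - cur[rest]
          k <- which.max(gains)
          if (gains[k] > 1e-12) {
            j <- i + k
            tmp <- perm[i]; perm[i] <- perm[j]; perm[j] <- tmp
            cur <- dots[cbind(seq_len(n), perm)]
            improved <- TRUE
          }
        }
        if (!improved) break
      }
    }
    perms[r, ] <- perm
  }
  structure(perms, class = c("spin_set", "matrix"), seed = seed)
}

# uniform random rotation in SO(3) via QR of a Gaussian matrix
random_rotation <- function() {
  qrd <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qrd)
  q <- q %*% diag(sign(diag(qr.R(qrd))))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

#' System-level enrichment under spin nulls
#'
#' Compares the observed mean of a regional value vector within each system
#' against the distribution of system means obtained from spun (spatially
#' permuted) copies of the vector. Two-sided p-values are computed around the
#' null median, with the add-one correction, and controlled across systems by
#' Benjamini-Hochberg FDR.
#'
#' @param values length-N regional value vector.
#' @param labels length-N system labels.
#' @param spins [spin_permutations()] set.
#' @param q FDR level (default 0.05).
#' @return data.frame with one row per system: observed mean, null median,
#'   p-value, and FDR significance; the largest rejected p is attached as
#'   attribute `"critical_p"`.
#' @export
system_enrichment <- function(values, labels, spins, q = 0.05) {
  labels <- factor(labels)
  sizes <- table(labels)
  if (any(sizes < 3)) stop("every system needs at least 3 parcels")
  n_perm <- nrow(spins)
  ind <- outer(labels, levels(labels), "==") * 1  # N x S membership
  obs <- as.numeric(crossprod(ind, values) / colSums(ind))
  spun <- matrix(values[t(spins)], nrow = n_perm, byrow = TRUE)  # n_perm x N
  null_means <- spun %*% ind / matrix(colSums(ind), n_perm, ncol(ind), byrow = TRUE)
  p <- numeric(length(obs))
  med <- numeric(length(obs))
  for (s in seq_along(obs)) {
    med[s] <- median(null_means[, s])
    # small tolerance so exact ties (e.g. constant maps) count as ties
    tol <- 1e-12 * max(1, abs(obs[s]))
    p[s] <- (1 + sum(abs(null_means[, s] - med[s]) >=
                       abs(obs[s] - med[s]) - tol)) / (1 + n_perm)
  }
  fdr <- bh_fdr(p, q)
  out <- data.frame(system = levels(labels), observed = obs,
                    null_median = med, p = p, significant = fdr$mask,
                    stringsAsFactors = FALSE)
  attr(out, "critical_p") <- fdr$critical
  out
}

#' Subject-level significance of a global fit
#'
#' One-sided spin-test p-value for the global R-squared of FC on one
#' predictor: each spin permutation is applied jointly to the predictor's
#' rows and columns, the fit is recomputed, and p is the add-one-corrected
#' fraction of null fits at least as large as the observed one.
#'
#' @param fc functional connectivity matrix.
#' @param predictor predictor matrix.
#' @param spins [spin_permutations()] set.
#' @return list with `observed`, `p`, and the vector of `null` R-squared
#'   values.
#' @export
subject_significance <- function(fc, predictor, spins) {
  y <- upper_tri_vec(as_square_matrix(fc))
  pm <- unclass(predictor)
  observed <- r2_or_na(y, upper_tri_vec(pm))
  nulls <- apply(spins, 1, function(perm) {
    r2_or_na(y, upper_tri_vec(pm[perm, perm]))
  })
  p <- (1 + sum(nulls >= observed, na.rm = TRUE)) / (1 + length(nulls))
  list(observed = observed, p = p, null = nulls)
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up FDR control. Returns the rejection mask and, in the reporting
#' style of spatial-enrichment analyses, the largest rejected raw p-value as
#' the "adjusted critical value".
#'
#' @param pvals vector of p-values in `[0, 1]` (NA allowed, never rejected).
#' @param q FDR level.
#' @return list with `mask` (logical) and `critical` (largest rejected p, or
#'   NA if nothing is rejected).
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) stop("empty p-value vector")
  adj <- p.adjust(pvals, method = "BH")
  mask <- !is.na(adj) & adj <= q
  critical <- if (any(mask)) max(pvals[mask]) else NA_real_
  list(mask = mask, critical = critical)
}

#' Floor-effect permutation null
#'
#' Estimates the R-squared floor for a regional fit by refitting against
#' uniformly permuted copies of the predictor row; the floor is the 95th
#' percentile of the null fits, and a region is flagged "at floor" when its
#' observed R-squared does not exceed that floor.
#'
#' @param y regional FC profile.
#' @param x regional predictor profile.
#' @param n_rep number of permutations (default 100).
#' @param seed optional RNG seed.
#' @param prob percentile used as the floor (default 0.95).
#' @return list with `observed`, `floor`, `at_floor`, and the `null` vector.
#' @export
floor_null <- function(y, x, n_rep = 100, seed = NULL, prob = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  observed <- r2_or_na(y, x)
  nulls <- vapply(seq_len(n_rep), function(i) {
    r2_or_na(y, sample(x))
  }, numeric(1))
  fl <- quantile(nulls, prob, na.rm = TRUE, names = FALSE)
  list(observed = observed, floor = fl,
       at_floor = is.na(observed) || observed <= fl, null = nulls)
}
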