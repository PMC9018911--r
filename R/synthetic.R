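#' Synthetic cohort configuration
#'
#' Collects the parameters of the synthetic connectome generator. The
#' defaults describe the regime the package's validation suite runs in: a
#' 100-node cortex-like parcellation on a 70 mm sphere, six spatially
#' contiguous systems, 15% connection density with exponentially
#' distance-decaying connection probability and weights, functional
#' connectivity generated as a noisy linear image of one planted predictor
#' per system, and a lifespan cohort whose planted coupling amplitude
#' declines linearly with age in designated "sensorimotor" systems.
#'
#' @param n_nodes number of parcels.
#' @param n_systems number of spatially contiguous systems.
#' @param density target binary connection density in (0, 1).
#' @param decay_rate exponential distance-decay rate (per mm) for both
#'   connection probability and weight magnitude.
#' @param planted_map named list or vector mapping system label (`"sys1"`,
#'   ...) to the battery label(s) whose matrix generates that system's FC
#'   rows; an entry with two labels plants a weighted pair (0.65/0.35).
#' @param noise_sd noise standard deviation relative to the (unit) signal SD.
#' @param n_subjects cohort size.
#' @param age_range age span in years.
#' @param age_decay fraction of coupling amplitude lost across the age range
#'   in the declining systems.
#' @param decline_systems system labels subject to the age decline.
#' @param baseline_weight weight of an age-stable geometric baseline
#'   component (the z-scored Euclidean-distance row) mixed into every FC
#'   row. Zero (the default) gives a pure planted-predictor construction;
#'   lifespan cohorts use a positive value so that, as the planted
#'   communication component declines with age, the geometric component
#'   overtakes it — mirroring how distance dependence dominates empirical FC.
#'   With planted amplitude a and baseline weight b, the planted predictor
#'   wins the regional argmax exactly when a > b (independent of their
#'   correlation), so the decline schedule sets the age at which regions
#'   flip to the geometric predictor.
#' @param squash_scale input scaling of the arctangent squash that bounds FC
#'   to (-1, 1); smaller values are more linear.
#' @return list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_nodes = 100,
                             n_systems = 6,
                             density = 0.15,
                             decay_rate = 0.03,
                             planted_map = NULL,
                             noise_sd = 0.1,
                             n_subjects = 20,
                             age_range = c(7, 85),
                             age_decay = 0.6,
                             decline_systems = c("sys1", "sys3"),
                             baseline_weight = 0,
                             squash_scale = 0.5) {
  if (is.null(planted_map)) {
    defaults <- c("mfpt-wei", "euc", "si-wei-4", "pt-wei-1", "mi-wei", "fg-bin-5")
    planted_map <- as.list(defaults[((seq_len(n_systems) - 1) %% length(defaults)) + 1])
    names(planted_map) <- paste0("sys", seq_len(n_systems))
  }
  planted_map <- as.list(planted_map)
  stopifnot(n_nodes > 0, n_systems > 0, density > 0, density < 1,
            decay_rate > 0, noise_sd >= 0, n_subjects > 0,
            age_range[2] > age_range[1], age_decay >= 0, age_decay <= 1)
  structure(list(n_nodes = n_nodes, n_systems = n_systems, density = density,
                 decay_rate = decay_rate, planted_map = planted_map,
                 noise_sd = noise_sd, n_subjects = n_subjects,
                 age_range = age_range, age_decay = age_decay,
                 decline_systems = decline_systems,
                 baseline_weight = baseline_weight,
                 squash_scale = squash_scale),
            class = "synthetic_config")
}

#' Lifespan study condition
#'
#' [synthetic_config()] preset for lifespan cohorts: a strong age-stable
#' geometric baseline (weight 0.6), a planted communication amplitude that
#' loses 80% of its strength across the age range in the decline systems
#' (so regions there flip to the geometric predictor around mid-life), and
#' noise large enough (SD 0.4) that the shrinking planted signal lowers the
#' maximum attainable regional R-squared with age. Together these reproduce
#' the three planted lifespan signatures: a negative residualized global
#' age correlation, a negative prevalence trend for the planted predictor
#' of the declining systems, and system-specific enrichment of negative
#' regional age correlations.
#'
#' @param n_nodes,n_subjects cohort dimensions.
#' @param ... further overrides passed to [synthetic_config()].
#' @return list of class `"synthetic_config"`.
#' @export
lifespan_config <- function(n_nodes = 100, n_subjects = 60, ...) {
  synthetic_config(n_nodes = n_nodes, n_subjects = n_subjects,
                   noise_sd = 0.4, baseline_weight = 0.6, age_decay = 0.8,
                   ...)
}

#' Generate synthetic parcel geometry
#'
#' Samples parcel centroids near a 70 mm sphere (uniform directions with
#' mild radial jitter), derives unit-sphere coordinates by normalization,
#' and assigns systems as spatially contiguous angular sectors (k-means on
#' the sphere coordinates). Hemisphere follows the sign of x.
#'
#' @param config [synthetic_config()].
#' @param seed optional RNG seed.
#' @return [parcel_geometry()] object.
#' @export
generate_geometry <- function(config = synthetic_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_nodes
  u <- runif(n, -1, 1)
  th <- runif(n, 0, 2 * pi)
  r <- sqrt(1 - u^2)
  dirs <- cbind(r * cos(th), r * sin(th), u)
  cen <- 70 * dirs + matrix(rnorm(3 * n, sd = 2), n, 3)
  sphere <- cen / sqrt(rowSums(cen^2))
  km <- kmeans(sphere, centers = config$n_systems, nstart = 10, iter.max = 100)
  parcel_geometry(cen, sphere_coords = sphere,
                  system_labels = paste0("sys", km$cluster))
}

# Prim's minimum spanning tree over a dense distance matrix; returns a
# 2-column edge index matrix
prim_mst <- function(d) {
  n <- nrow(d)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- d[1, ]
  from <- rep(1L, n)
  edges <- matrix(0L, n - 1, 2)
  for (k in seq_len(n - 1)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best[cand])]
    edges[k, ] <- c(from[v], v)
    in_tree[v] <- TRUE
    upd <- !in_tree & d[v, ] < best
    best[upd] <- d[v, upd]
    from[upd] <- v
  }
  edges
}

#' Generate synthetic structural connectivity
#'
#' Edges are Bernoulli with probability proportional to
#' `exp(-decay_rate * distance)`, scaled so the expected density matches the
#' target; weights are log-normal, scaled by the same exponential distance
#' decay. A minimum spanning tree over distance is added so the graph is
#' always connected.
#'
#' @param geometry [parcel_geometry()].
#' @param config [synthetic_config()].
#' @param seed optional RNG seed.
#' @return validated structural connectivity matrix.
#' @export
generate_sc <- function(geometry, config = synthetic_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- euclidean_matrix(geometry)
  n <- nrow(d)
  ut <- upper.tri(d)
  f <- exp(-config$decay_rate * d[ut])
  k <- stats::uniroot(function(k) mean(pmin(k * f, 1)) - config$density,
                      c(1e-8, 1e8), tol = 1e-10)$root
  pvec <- pmin(k * f, 1)
  edge <- rbinom(length(pvec), 1, pvec)
  w <- rlnorm(length(pvec), meanlog = 0, sdlog = 0.75) *
    exp(-config$decay_rate * d[ut])
  a <- matrix(0, n, n)
  a[ut] <- edge * w
  a <- a + t(a)
  mst <- prim_mst(d)
  for (e in seq_len(nrow(mst))) {
    i <- mst[e, 1]; j <- mst[e, 2]
    if (a[i, j] == 0) {
      wij <- rlnorm(1, 0, 0.75) * exp(-config$decay_rate * d[i, j])
      a[i, j] <- a[j, i] <- wij
    }
  }
  validate_connectivity(a, kind = "structural")
}

#' Compute a single predictor by battery label
#'
#' Parses a battery label (e.g. `"fg-wei-2.5"`, `"si-wei-0.25"`,
#' `"mfpt-bin"`, `"euc"`) and computes the corresponding predictor matrix
#' with zeroed diagonal. Used by the synthetic generator so that cohorts
#' only pay for the predictors they plant.
#'
#' @param sc structural connectivity matrix.
#' @param geometry [parcel_geometry()].
#' @param label battery label.
#' @return N x N predictor matrix.
#' @export
compute_predictor <- function(sc, geometry, label) {
  parts <- strsplit(label, "-", fixed = TRUE)[[1]]
  fam <- parts[1]
  variant <- if (length(parts) >= 2) parts[2] else NA_character_
  param <- if (length(parts) >= 3) as.numeric(parts[3]) else NA_real_
  vlong <- c(bin = "binary", wei = "weighted")[variant]
  m <- switch(fam,
    fg = flow_graph(sc, param, vlong),
    nav = navigation(sc, geometry)[[paste0("nav_", variant)]],
    comm = communicability(sc, vlong),
    pt = path_transitivity(sc, if (variant == "bin") NULL else param),
    mi = matching_index(sc, vlong),
    pl = shortest_path_length(sc, if (variant == "bin") NULL else param),
    cos = cosine_similarity(sc, vlong),
    si = search_information(sc, if (variant == "bin") NULL else param),
    mfpt = mean_first_passage_time(sc, vlong),
    euc = euclidean_matrix(geometry),
    stop("unknown predictor label: ", label)
  )
  m <- unclass(m)
  attr(m, "pred") <- NULL
  diag(m) <- 0
  m
}

#' Generate synthetic functional connectivity with planted structure
#'
#' For each region, the FC row is an affine image of the region's planted
#' predictor row (z-scored over finite entries; non-finite entries take the
#' row's maximum finite value) scaled by the region's coupling amplitude,
#' plus Gaussian noise with SD `noise_sd` times the signal SD. The matrix is
#' symmetrized by averaging and bounded to (-1, 1) by a scaled arctangent
#' squash that preserves rank structure. The planted label per region is
#' recorded as attribute `"truth"`.
#'
#' @param sc structural connectivity matrix.
#' @param geometry [parcel_geometry()].
#' @param config [synthetic_config()].
#' @param seed optional RNG seed.
#' @param amplitudes optional per-region coupling amplitudes (default 1).
#' @param predictors optional named list of precomputed predictor matrices.
#' @return FC matrix with attribute `"truth"` (data.frame of region, system,
#'   planted label(s), amplitude).
#' @export
generate_fc <- function(sc, geometry, config = synthetic_config(), seed = NULL,
                        amplitudes = NULL, predictors = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sys <- as.character(geometry$system_labels)
  n <- length(sys)
  if (is.null(amplitudes)) amplitudes <- rep(1, n)
  pmap <- config$planted_map
  needed <- unique(unlist(pmap[unique(sys)]))
  if (is.null(predictors)) predictors <- list()
  for (lb in setdiff(needed, names(predictors))) {
    predictors[[lb]] <- compute_predictor(sc, geometry, lb)
  }
  euc_base <- if (config$baseline_weight > 0) euclidean_matrix(geometry)
  raw <- matrix(0, n, n)
  for (i in seq_len(n)) {
    labs <- pmap[[sys[i]]]
    wts <- if (length(labs) == 2) c(0.65, 0.35) else 1
    sig <- rep(0, n)
    for (k in seq_along(labs)) {
      x <- predictors[[labs[k]]][i, ]
      x[i] <- NA
      fin <- is.finite(x)
      if (!any(fin)) stop("planted predictor row is non-finite everywhere")
      x[!fin & !is.na(x)] <- max(x[fin], na.rm = TRUE)
      z <- (x - mean(x, na.rm = TRUE)) / sd(x, na.rm = TRUE)
      z[i] <- 0
      sig <- sig + wts[k] * z
    }
    if (config$baseline_weight > 0) {
      eu <- euc_base[i, ]
      eu[i] <- NA
      zb <- (eu - mean(eu, na.rm = TRUE)) / sd(eu, na.rm = TRUE)
      zb[i] <- 0
      sig <- amplitudes[i] * sig + config$baseline_weight * zb
    } else {
      sig <- amplitudes[i] * sig
    }
    raw[i, ] <- sig + rnorm(n, sd = config$noise_sd)
    raw[i, i] <- 0
  }
  raw <- (raw + t(raw)) / 2
  fc <- (2 / pi) * atan(config$squash_scale * raw)
  diag(fc) <- 0
  truth <- data.frame(region = seq_len(n), system = sys,
                      planted = vapply(pmap[sys], paste, "", collapse = "+"),
                      amplitude = amplitudes, stringsAsFactors = FALSE)
  structure(fc, truth = truth)
}

#' Generate a synthetic lifespan cohort
#'
#' Draws subject ages uniformly over the configured range, resamples each
#' subject's SC around a shared group template (multiplicative log-normal
#' weight jitter on a fixed edge set, so every subject stays connected), and
#' generates FC with a planted coupling amplitude that declines linearly
#' with age — by `age_decay` across the full range — in the designated
#' decline systems and stays flat elsewhere. Nuisance covariates are drawn
#' with mild age correlation (mean framewise displacement increases, frame
#' count decreases) to exercise residualization.
#'
#' @param config [synthetic_config()].
#' @param seed optional RNG seed.
#' @return list with `geometry`, `sc` (list of per-subject matrices), `fc`
#'   (list), `cohort` (data.frame of covariates), `truth` (planted map and
#'   decline regions).
#' @export
generate_cohort <- function(config = synthetic_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  geometry <- generate_geometry(config)
  template <- generate_sc(geometry, config)
  n <- config$n_nodes
  ns <- config$n_subjects
  sys <- as.character(geometry$system_labels)
  declining <- sys %in% config$decline_systems
  ages <- runif(ns, config$age_range[1], config$age_range[2])
  rel_age <- (ages - config$age_range[1]) / diff(config$age_range)
  euc <- euclidean_matrix(geometry)
  ut <- upper.tri(template)
  sc_list <- fc_list <- vector("list", ns)
  sex <- rbinom(ns, 1, 0.5)
  visit_time <- runif(ns, 8, 18)
  # mild age correlation (|r| ~ 0.3) so residualization is exercised without
  # the nuisance set absorbing the age effect itself
  n_frames <- pmax(100L, round(rnorm(ns, 700 - 0.5 * ages, 60)))
  mean_fd <- pmax(0.02, 0.08 + 0.0003 * ages + rnorm(ns, sd = 0.02))
  total_weight <- binary_density <- numeric(ns)
  deg_bin <- deg_wei <- matrix(0, ns, n)
  for (s in seq_len(ns)) {
    a <- unclass(template)
    jit <- matrix(0, n, n)
    jit[ut] <- rnorm(sum(ut), sd = 0.3)
    jit <- jit + t(jit)
    a <- a * exp(jit)
    sc_list[[s]] <- a
    amp <- ifelse(declining, 1 - config$age_decay * rel_age[s], 1)
    fc_list[[s]] <- generate_fc(a, geometry, config, amplitudes = amp,
                                predictors = list(euc = euc))
    total_weight[s] <- sum(a) / 2
    binary_density[s] <- mean(a[ut] > 0)
    deg_bin[s, ] <- rowSums(a > 0)
    deg_wei[s, ] <- rowSums(a)
  }
  cohort <- data.frame(subject_id = seq_len(ns), age = ages, sex = sex,
                       visit_time = visit_time, n_frames = n_frames,
                       mean_fd = mean_fd, total_weight = total_weight,
                       binary_density = binary_density)
  truth <- list(planted_map = config$planted_map,
                decline_systems = config$decline_systems,
                decline_regions = which(declining),
                amplitude_ratio = 1 - config$age_decay)
  list(geometry = geometry, sc = sc_list, fc = fc_list, cohort = cohort,
       degree_bin = deg_bin, degree_wei = deg_wei, truth = truth)
}

#' Tiny hand-checkable fixture graphs
#'
#' A named set of small graphs with coordinates, used throughout the test
#' suite as oracle inputs: a 2-node edge, a 3-node path, the triangle K3, a
#' 4-cycle, a 5-node star, a weighted triangle with weights {0.1, 1, 1}, and
#' a deterministic 10-node geometric graph (golden-angle spiral points,
#' 3-nearest-neighbor edges plus a spanning tree).
#'
#' @return named list; each element has `sc` (validated matrix) and
#'   `geometry`.
#' @export
fixture_graphs <- function() {
  mk <- function(edges, n, coords, weights = NULL) {
    a <- matrix(0, n, n)
    if (is.null(weights)) weights <- rep(1, nrow(edges))
    for (e in seq_len(nrow(edges))) {
      a[edges[e, 1], edges[e, 2]] <- a[edges[e, 2], edges[e, 1]] <- weights[e]
    }
    list(sc = validate_connectivity(a, "structural"),
         geometry = parcel_geometry(coords))
  }
  out <- list()
  out$edge2 <- mk(rbind(c(1, 2)), 2, rbind(c(-10, 0, 0), c(10, 0, 0)))
  out$path3 <- mk(rbind(c(1, 2), c(2, 3)), 3,
                  rbind(c(-20, 0, 5), c(0, 0, 25), c(20, 0, 5)))
  out$k3 <- mk(rbind(c(1, 2), c(2, 3), c(1, 3)), 3,
               rbind(c(0, 10, 0), c(10, -5, 0), c(-10, -5, 0)))
  out$cycle4 <- mk(rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)), 4,
                   rbind(c(10, 10, 0), c(10, -10, 0), c(-10, -10, 0), c(-10, 10, 0)))
  out$star5 <- mk(rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5)), 5,
                  rbind(c(0, 0, 10), c(10, 0, 0), c(0, 10, 0), c(-10, 0, 0), c(0, -10, 0)))
  out$wtri <- mk(rbind(c(1, 2), c(2, 3), c(1, 3)), 3,
                 rbind(c(0, 10, 0), c(10, -5, 0), c(-10, -5, 0)),
                 weights = c(1, 1, 0.1))
  # deterministic 10-node geometric graph: golden-angle spiral on a sphere
  n <- 10
  idx <- seq_len(n)
  z <- 1 - (2 * idx - 1) / n
  phi <- idx * pi * (3 - sqrt(5))
  rr <- sqrt(1 - z^2)
  coords <- 40 * cbind(rr * cos(phi), rr * sin(phi), z)
  d <- as.matrix(dist(coords))
  a <- matrix(0, n, n)
  for (i in idx) {
    nb <- order(d[i, -i])[1:3]
    nb <- seq_len(n)[-i][nb]
    a[i, nb] <- a[nb, i] <- 1 / (1 + d[i, nb] / 40)
  }
  mst <- prim_mst(d)
  for (e in seq_len(nrow(mst))) {
    i <- mst[e, 1]; j <- mst[e, 2]
    if (a[i, j] == 0) a[i, j] <- a[j, i] <- 1 / (1 + d[i, j] / 40)
  }
  out$geo10 <- list(sc = validate_connectivity(a, "structural"),
                    geometry = parcel_geometry(coords))
  out
}
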