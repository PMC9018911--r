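#' Validate and canonicalize a connectivity matrix
#'
#' Checks that a matrix is square, finite, and symmetric to within a small
#' tolerance, symmetrizes it as `(M + t(M))/2`, and zeroes the diagonal.
#' Structural matrices must additionally be nonnegative and describe a
#' connected graph (a single component); self-connections are never
#' meaningful and are removed here once and for all.
#'
#' @param m numeric square matrix of connection weights.
#' @param kind one of `"structural"`, `"functional"`, `"predictor"`.
#'   Nonnegativity and connectedness are enforced for `"structural"` only.
#' @param tol asymmetry tolerance; entries with
#'   `max(|M - t(M)|) > tol` raise an error rather than being silently
#'   averaged. The default is loose enough that delimited-text round trips
#'   never trip it.
#' @return the validated matrix with class `"connectivity_matrix"` and
#'   attribute `kind`.
#' @export
validate_connectivity <- function(m, kind = c("structural", "functional", "predictor"),
                                  tol = 1e-8) {
  kind <- match.arg(kind)
  if (!is.matrix(m) || !is.numeric(m)) stop("input must be a numeric matrix")
  if (nrow(m) != ncol(m)) stop("connectivity matrix must be square")
  if (any(!is.finite(m))) stop("connectivity matrix must be finite")
  asym <- max(abs(m - t(m)))
  if (asym > tol) {
    stop(sprintf("matrix asymmetry %.3g exceeds tolerance %.3g", asym, tol))
  }
  m <- (m + t(m)) / 2
  diag(m) <- 0
  if (kind == "structural") {
    if (any(m < 0)) stop("structural weights must be nonnegative")
    if (!is_connected(m)) stop("structural graph is disconnected")
  }
  structure(m, class = c("connectivity_matrix", "matrix"), kind = kind)
}

# single-component check by breadth-first search on the nonzero pattern
is_connected <- function(m) {
  n <- nrow(m)
  if (n == 0L) return(FALSE)
  seen <- logical(n)
  seen[1L] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nb <- which(colSums(m[frontier, , drop = FALSE] != 0) > 0 & !seen)
    seen[nb] <- TRUE
    frontier <- nb
  }
  all(seen)
}

#' Weight-to-cost transform
#'
#' Converts connection weights (affinities) to traversal costs via
#' `C_ij = A_ij^-gamma`. Absent edges (zero weight) become infinite cost so
#' that shortest-path routines handle sparse graphs uniformly; the diagonal
#' stays zero.
#'
#' @param sc structural connectivity matrix (nonnegative, zero diagonal).
#' @param gamma positive exponent. The battery uses
#'   `c(0.125, 0.25, 0.5, 1, 2, 4)`; any positive value is accepted.
#' @return cost matrix with attribute `gamma`.
#' @export
weight_to_cost <- function(sc, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    stop("gamma must be a single positive number")
  }
  sc <- as_square_matrix(sc)
  cost <- ifelse(sc > 0, sc^(-gamma), Inf)
  diag(cost) <- 0
  attr(cost, "gamma") <- gamma
  cost
}

as_square_matrix <- function(m) {
  m <- unclass(m)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  m
}

#' Parcel geometry container
#'
#' Bundles parcel centroid coordinates (mm), unit-sphere coordinates used by
#' the spin test, categorical system labels, and hemisphere labels.
#'
#' @param centroids N x 3 numeric matrix of centroid coordinates (mm).
#' @param sphere_coords N x 3 numeric matrix of unit-norm sphere coordinates;
#'   defaults to row-normalized centroids.
#' @param system_labels length-N vector of system labels (coerced to factor).
#' @param hemisphere length-N vector of hemisphere labels; defaults to the
#'   sign of the x coordinate.
#' @return list of class `"parcel_geometry"`.
#' @export
parcel_geometry <- function(centroids, sphere_coords = NULL,
                            system_labels = NULL, hemisphere = NULL) {
  centroids <- as.matrix(centroids)
  dimnames(centroids) <- NULL
  stopifnot(ncol(centroids) == 3L)
  n <- nrow(centroids)
  if (is.null(sphere_coords)) {
    nrm <- sqrt(rowSums(centroids^2))
    if (any(nrm == 0)) stop("cannot normalize a zero centroid onto the sphere")
    sphere_coords <- centroids / nrm
  }
  sphere_coords <- as.matrix(sphere_coords)
  dimnames(sphere_coords) <- NULL
  stopifnot(nrow(sphere_coords) == n, ncol(sphere_coords) == 3L)
  nrm <- sqrt(rowSums(sphere_coords^2))
  if (any(abs(nrm - 1) > 1e-8)) stop("sphere coordinates must have unit norm")
  if (is.null(system_labels)) system_labels <- rep("all", n)
  if (is.null(hemisphere)) hemisphere <- ifelse(centroids[, 1] < 0, "L", "R")
  structure(
    list(centroids = centroids, sphere_coords = sphere_coords,
         system_labels = factor(system_labels), hemisphere = hemisphere),
    class = "parcel_geometry"
  )
}

#' @export
print.parcel_geometry <- function(x, ...) {
  cat(sprintf("parcel geometry: %d parcels, %d systems\n",
              nrow(x$centroids), nlevels(x$system_labels)))
  invisible(x)
}

#' Read a connectivity matrix from delimited text
#'
#' Matrix files are plain delimited text (tab or comma), N rows by N columns,
#' no header, one file per subject per matrix. NaN entries are rejected.
#'
#' @param path file path.
#' @param kind passed to [validate_connectivity()].
#' @return validated connectivity matrix.
#' @export
read_connectivity <- function(path, kind = "structural") {
  m <- as.matrix(read.table(path, header = FALSE, sep = guess_sep(path)))
  dimnames(m) <- NULL
  if (any(is.na(m))) stop("matrix file contains NA/NaN entries: ", path)
  validate_connectivity(m, kind = kind)
}

#' Write a matrix as delimited text
#'
#' @param m numeric matrix.
#' @param path destination file.
#' @param sep field separator (default tab).
#' @export
write_matrix <- function(m, path, sep = "\t") {
  write.table(unclass(m), path, sep = sep, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read parcel geometry from delimited text
#'
#' Expects a centroid file with columns x,y,z, optionally a sphere-coordinate
#' file with columns sx,sy,sz, and optionally a labels file with one system
#' label per line, all row-matched to the matrix files.
#'
#' @param centroid_path path to the centroid table.
#' @param sphere_path optional path to the unit-sphere coordinate table.
#' @param labels_path optional path to the system labels file.
#' @return [parcel_geometry()] object.
#' @export
read_geometry <- function(centroid_path, sphere_path = NULL, labels_path = NULL) {
  cen <- as.matrix(read.table(centroid_path, header = FALSE, sep = guess_sep(centroid_path)))
  sph <- if (!is.null(sphere_path)) {
    as.matrix(read.table(sphere_path, header = FALSE, sep = guess_sep(sphere_path)))
  }
  lab <- if (!is.null(labels_path)) readLines(labels_path)
  parcel_geometry(cen, sphere_coords = sph, system_labels = lab)
}

guess_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl(",", first, fixed = TRUE)) "," else ""
}
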