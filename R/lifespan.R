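#' Nuisance residualization
#'
#' OLS residuals of a per-subject value vector on a set of nuisance
#' covariates plus an intercept. Covariates are z-scored for conditioning
#' (which leaves the residual span unchanged); constant and collinear
#' columns are dropped with a warning. The residuals are orthogonal to every
#' retained covariate.
#'
#' @param values numeric vector, one entry per subject.
#' @param covariates matrix or data.frame of nuisance covariates (factors
#'   are expanded to indicators).
#' @return residual vector.
#' @export
residualize <- function(values, covariates) {
  x <- covariate_matrix(covariates)
  if (ncol(x) >= length(values) - 2) stop("too many covariates for the sample")
  keep <- apply(x, 2, function(cl) sd(cl) > 0)
  if (!all(keep)) {
    warning("dropping constant covariate column(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
    x <- x[, keep, drop = FALSE]
  }
  x <- scale(x)
  design <- cbind(1, x)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    drop_idx <- qrd$pivot[-seq_len(qrd$rank)]
    warning("dropping collinear covariate column(s)")
    design <- design[, -drop_idx, drop = FALSE]
  }
  as.numeric(qr.resid(qr(design), values))
}

covariate_matrix <- function(covariates) {
  if (is.data.frame(covariates)) {
    x <- stats::model.matrix(~ . - 1, data = covariates)
  } else {
    x <- as.matrix(covariates)
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("cov", seq_len(ncol(x)))
  x
}

#' Correlation of residualized values with age
#'
#' Pearson correlation with a two-sided t-based p-value.
#'
#' @param residuals per-subject residual vector (see [residualize()]).
#' @param age per-subject ages.
#' @return list with `r` and `p`.
#' @export
age_correlation <- function(residuals, age) {
  if (length(residuals) < 10) stop("need at least 10 subjects")
  if (sd(residuals) == 0 || sd(age) == 0) stop("zero-variance input")
  ct <- cor.test(residuals, age, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Age trend of optimal-predictor prevalence
#'
#' For each subject, the fraction of regions best explained by each
#' predictor (a length-P vector summing to 1); each predictor's fraction is
#' residualized against the nuisance covariates and correlated with age,
#' with Benjamini-Hochberg FDR control across predictors.
#'
#' @param best_labels subjects x regions character matrix of best labels.
#' @param age per-subject ages.
#' @param covariates nuisance covariates (subjects x k).
#' @param labels battery label set.
#' @param q FDR level.
#' @return data.frame with one row per predictor: `label`, `r`, `p`,
#'   `significant`; subject-level fractions attached as attribute
#'   `"fractions"`.
#' @export
prevalence_trend <- function(best_labels, age, covariates, labels, q = 0.05) {
  ns <- nrow(best_labels)
  frac <- t(vapply(seq_len(ns), function(s) {
    tab <- table(factor(best_labels[s, ], levels = labels))
    as.numeric(tab) / sum(tab)
  }, numeric(length(labels))))
  colnames(frac) <- labels
  r <- p <- rep(NA_real_, length(labels))
  for (j in seq_along(labels)) {
    if (sd(frac[, j]) == 0) next  # predictor never/always optimal
    res <- residualize(frac[, j], covariates)
    if (sd(res) == 0) next
    ct <- age_correlation(res, age)
    r[j] <- ct$r
    p[j] <- ct$p
  }
  fdr <- bh_fdr(p, q)
  out <- data.frame(label = labels, r = r, p = p, significant = fdr$mask,
                    stringsAsFactors = FALSE)
  attr(out, "fractions") <- frac
  attr(out, "critical_p") <- fdr$critical
  out
}

#' Regional age correlation map
#'
#' Per-region correlation of coupling magnitude (maximum regional R-squared)
#' with age after residualizing nuisance covariates; for regional analyses
#' the covariate set additionally includes the region's per-subject binary
#' and weighted degrees when supplied. Feed the resulting map to
#' [system_enrichment()] for system-level tests.
#'
#' @param max_r2 subjects x regions matrix of coupling magnitudes.
#' @param age per-subject ages.
#' @param covariates global nuisance covariates (subjects x k).
#' @param degree_bin,degree_wei optional subjects x regions matrices of
#'   per-subject node degrees appended to the covariates region by region.
#' @return list with vectors `r` and `p`, one entry per region.
#' @export
regional_age_map <- function(max_r2, age, covariates,
                             degree_bin = NULL, degree_wei = NULL) {
  n_reg <- ncol(max_r2)
  covs <- covariate_matrix(covariates)
  r <- p <- rep(NA_real_, n_reg)
  for (i in seq_len(n_reg)) {
    x <- covs
    if (!is.null(degree_bin)) x <- cbind(x, deg_bin = degree_bin[, i])
    if (!is.null(degree_wei)) x <- cbind(x, deg_wei = degree_wei[, i])
    res <- suppressWarnings(residualize(max_r2[, i], x))
    if (sd(res) == 0) next
    ct <- age_correlation(res, age)
    r[i] <- ct$r
    p[i] <- ct$p
  }
  list(r = r, p = p)
}

#' Age-binned prevalence analysis
#'
#' Splits subjects into equal-count age bins and summarizes each bin: median
#' age, subject count, and the mean of each supplied per-subject summary
#' column; reports the Spearman correlation of bin median ages with each
#' bin-level mean.
#'
#' @param age per-subject ages.
#' @param values per-subject summary vector or matrix (subjects x k).
#' @param n_bins number of equal-count bins (default 10).
#' @return list with `bins` (data.frame of per-bin summaries) and `trend`
#'   (Spearman rho of each summary column with bin median age).
#' @export
age_binned_analysis <- function(age, values, n_bins = 10) {
  if (n_bins < 2) stop("need at least 2 bins")
  values <- as.matrix(values)
  ranks <- rank(age, ties.method = "first")
  bin <- ceiling(ranks * n_bins / length(age))
  counts <- tabulate(bin, n_bins)
  if (any(counts < 3)) stop("bins with fewer than 3 subjects")
  med_age <- vapply(seq_len(n_bins), function(b) median(age[bin == b]), numeric(1))
  means <- t(vapply(seq_len(n_bins),
                    function(b) colMeans(values[bin == b, , drop = FALSE]),
                    numeric(ncol(values))))
  trend <- apply(means, 2, function(cl) {
    if (sd(cl) == 0) NA_real_ else cor(med_age, cl, method = "spearman")
  })
  bins <- data.frame(bin = seq_len(n_bins), n = counts, median_age = med_age)
  list(bins = cbind(bins, means), trend = trend)
}
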