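#' PCA and K-means tolerance typing in retention space
#'
#' Principal components of the standardized retention matrix summarise the
#' dominant axes of stress response; K-means (k = 3 by default, 10 seeded
#' restarts) on the leading component scores partitions accessions into
#' tolerant / intermediate / sensitive phenotypic groups. Two conventions
#' remove arbitrary degrees of freedom: PC1's sign is oriented so it
#' correlates positively with the STS (tolerant accessions have higher PC1
#' scores), and clusters are labelled by descending mean STS so the class
#' names never depend on K-means' internal label order.
#'
#' @param fit an `sts` fit (its z-matrix and score are used).
#' @param k number of clusters.
#' @param n_components PC scores fed to K-means (default 2).
#' @param seed integer seed for the K-means restarts.
#' @return Object of class `sts_typing`: data frame `scores` (accession,
#'   PC1, PC2, cluster, class), `variance_explained`, the cluster-to-class
#'   `mapping` (by descending mean STS), and the full `prcomp` object.
#' @export
pca_typing <- function(fit, k = 3, n_components = 2, seed = NULL) {
  if (!inherits(fit, "sts")) stopf("fit must be an sts object")
  z <- fit$z
  if (anyNA(z)) {
    # PCA needs complete cells; median-impute the (few) missing retentions
    z <- impute_col_median(z)
  }
  if (ncol(z) < 2L) stopf("typing needs at least 2 trait columns")
  if (!is_count(k) || k >= nrow(z))
    stopf("k must be a positive integer below the number of accessions")
  pc <- stats::prcomp(z, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  if (stats::cor(pc$x[, 1], fit$score) < 0) {
    pc$x[, 1] <- -pc$x[, 1]
    pc$rotation[, 1] <- -pc$rotation[, 1]
  }
  n_components <- min(n_components, ncol(pc$x))
  km <- with_seed(seed,
                  stats::kmeans(pc$x[, seq_len(n_components), drop = FALSE],
                                centers = k, nstart = 10))
  mean_sts <- tapply(fit$score, km$cluster, mean)
  class_names <- if (k == 3) c("tolerant", "intermediate", "sensitive")
                 else sprintf("class%d", seq_len(k))
  mapping <- stats::setNames(class_names,
                             names(sort(mean_sts, decreasing = TRUE)))
  scores <- data.frame(accession = rownames(z),
                       PC1 = pc$x[, 1],
                       PC2 = if (ncol(pc$x) >= 2) pc$x[, 2] else 0,
                       cluster = km$cluster,
                       class = unname(mapping[as.character(km$cluster)]),
                       stringsAsFactors = FALSE)
  rownames(scores) <- NULL
  structure(list(scores = scores, variance_explained = ve,
                 mapping = mapping, prcomp = pc, kmeans = km),
            class = "sts_typing")
}

#' @export
print.sts_typing <- function(x, ...) {
  cat(sprintf("PCA + K-means typing: PC1 %.1f%%, PC2 %.1f%% of variance\n",
              100 * x$variance_explained[1],
              100 * sum(x$variance_explained[2])))
  print(table(x$scores$class))
  invisible(x)
}

impute_col_median <- function(m) {
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    if (any(miss)) m[miss, j] <- stats::median(m[, j], na.rm = TRUE)
  }
  m
}

#' Pairwise trait correlations on the retention matrix
#'
#' Pairwise-complete Pearson correlations between retention columns. Strongly
#' correlated blocks (e.g. germination index, rate and vigor index) identify
#' traits that respond synergistically under stress — the redundancy that
#' makes the composite score robust.
#'
#' @param m a `retention_matrix` or numeric matrix.
#' @return Symmetric correlation matrix with unit diagonal; `NA` where fewer
#'   than 3 complete pairs or a constant column make r undefined.
#' @export
trait_correlations <- function(m) {
  if (inherits(m, "retention_matrix")) m <- m$R
  m <- as.matrix(m)
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  npair <- crossprod(!is.na(m))
  r[npair < 3] <- NA_real_
  diag(r) <- 1
  r
}

#' Cross-environment trait correlations
#'
#' For each trait, the Pearson correlation across accessions between its raw
#' control value and its raw stress value, with the two-sided test p-value.
#' Strong positive correlations mean the accession ranking for that trait is
#' preserved under stress, supporting control-condition pre-screening.
#'
#' @param traits a [build_trait_table()] result.
#' @param treatments control / stress labels, control first.
#' @return Data frame: trait, r, p, n (complete pairs); `NA` where fewer than
#'   3 complete pairs exist.
#' @export
cross_env_correlation <- function(traits, treatments = c("CK", "NaCl150")) {
  check_columns(traits, c("accession", "treatment", "trait", "value"),
                "trait table")
  trts <- sort(unique(traits$trait))
  out <- data.frame(trait = trts, r = NA_real_, p = NA_real_, n = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(trts)) {
    d <- traits[traits$trait == trts[i], , drop = FALSE]
    dck <- d[d$treatment == treatments[1], , drop = FALSE]
    dsa <- d[d$treatment == treatments[2], , drop = FALSE]
    ck <- stats::setNames(dck$value, dck$accession)
    salt <- stats::setNames(dsa$value, dsa$accession)
    common <- intersect(names(ck)[!is.na(ck)], names(salt)[!is.na(salt)])
    out$n[i] <- length(common)
    if (length(common) >= 3 &&
        stats::sd(ck[common]) > 0 && stats::sd(salt[common]) > 0) {
      ct <- stats::cor.test(ck[common], salt[common])
      out$r[i] <- unname(ct$estimate)
      out$p[i] <- ct$p.value
    }
  }
  out
}

#' Canonical correlation of control and stress phenotype spaces
#'
#' Measures how much of the multi-trait phenotypic structure is shared
#' between environments. Both matrices are column-standardized, near-constant
#' columns dropped, and the canonical correlations computed as the singular
#' values of the whitened cross-covariance
#' \eqn{S_{xx}^{-1/2} S_{xy} S_{yy}^{-1/2}}, with a small ridge added to the
#' within-set covariances to guard against collinearity (common with
#' replicate-suffixed trait panels).
#'
#' @param ck_matrix,stress_matrix numeric matrices sharing accession rows
#'   (accessions x traits) for the control and stress environments.
#' @param ridge ridge added to the diagonal of each within-set covariance.
#' @param sd_tol columns with sd below this are dropped as near-constant.
#' @return Object of class `cca_consistency`: `cor` (canonical correlations,
#'   non-increasing, in [0, 1]), `x_scores`, `y_scores` (canonical variates),
#'   and the retained column names.
#' @export
cca_consistency <- function(ck_matrix, stress_matrix, ridge = 1e-8,
                            sd_tol = 1e-10) {
  X <- as.matrix(ck_matrix)
  Y <- as.matrix(stress_matrix)
  if (nrow(X) != nrow(Y)) stopf("matrices must share accession rows")
  keep <- function(m) {
    sdv <- apply(m, 2, stats::sd)
    which(!is.na(sdv) & sdv > sd_tol)
  }
  kx <- keep(X); ky <- keep(Y)
  if (length(kx) == 0L || length(ky) == 0L)
    stopf("no non-constant columns to correlate")
  X <- scale(X[, kx, drop = FALSE])
  Y <- scale(Y[, ky, drop = FALSE])
  n <- nrow(X)
  d <- min(ncol(X), ncol(Y), n - 1L)
  if (d < min(ncol(X), ncol(Y)))
    warnf("fewer accessions than columns; reducing to %d component(s)", d)

  inv_sqrt <- function(S) {
    e <- eigen(S, symmetric = TRUE)
    vals <- pmax(e$values, ridge)
    e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors)
  }
  Sxx <- crossprod(X) / (n - 1) + ridge * diag(ncol(X))
  Syy <- crossprod(Y) / (n - 1) + ridge * diag(ncol(Y))
  Sxy <- crossprod(X, Y) / (n - 1)
  K <- inv_sqrt(Sxx) %*% Sxy %*% inv_sqrt(Syy)
  sv <- svd(K, nu = d, nv = d)
  cors <- pmin(pmax(sv$d[seq_len(d)], 0), 1)
  a <- inv_sqrt(Sxx) %*% sv$u
  b <- inv_sqrt(Syy) %*% sv$v
  structure(list(cor = cors,
                 x_scores = X %*% a, y_scores = Y %*% b,
                 x_cols = colnames(X), y_cols = colnames(Y)),
            class = "cca_consistency")
}

#' @export
print.cca_consistency <- function(x, ...) {
  cat("Canonical correlation of CK vs stress phenotype spaces\n")
  cat("  correlations:", paste(sprintf("%.3f", utils::head(x$cor, 5)),
                               collapse = ", "), "\n")
  invisible(x)
}
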