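#' Fit the composite Salt Tolerance Score
#'
#' The Salt Tolerance Score (STS) of an accession is the mean of its
#' column-Z-scored trait retentions: each retention column is standardized to
#' mean 0 / sd 1 (so no trait dominates through its scale) and the per-row
#' average summarises how well the accession maintains its phenotype under
#' stress relative to the cohort. Higher scores mean more tolerant. Because
#' z-scores absorb any affine rescaling of a raw trait, the STS is invariant
#' to trait units.
#'
#' Missing cells are skipped in the row mean (no imputation); accessions with
#' no observed trait at all are dropped with a warning. Ranks are 1 = most
#' tolerant, with ties broken by accession label for reproducibility.
#'
#' @param x a `retention_matrix` from [build_retention_matrix()], a
#'   `trait_table` from [build_trait_table()] (the retention matrix is then
#'   built internally), or a numeric matrix of already z-scored columns.
#' @param ... passed to [build_retention_matrix()] for the trait-table
#'   method (e.g. `treatments`).
#' @return An object of class `sts`: list with `score` (named vector),
#'   `rank`, `z` (the standardized retention matrix), `retention` (the
#'   `retention_matrix`, when available) and `call`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_accessions = 12, rng_seed = 1))
#' traits <- build_trait_table(cohort$germination, cohort$biomass)
#' fit <- sts(build_retention_matrix(traits))
#' head(sort(coef(fit), decreasing = TRUE))
#' @export
sts <- function(x, ...) UseMethod("sts")

#' @rdname sts
#' @export
sts.retention_matrix <- function(x, ...) {
  z <- zscore_columns(x)
  out <- sts_from_z(z, match.call())
  out$retention <- x
  out
}

#' @rdname sts
#' @export
sts.trait_table <- function(x, ...) {
  m <- build_retention_matrix(x, ...)
  out <- sts(m)
  out$call <- match.call()
  out
}

#' @rdname sts
#' @export
sts.matrix <- function(x, ...) sts_from_z(x, match.call())

#' @rdname sts
#' @export
sts.default <- function(x, ...) {
  stopf("no sts() method for class <%s>", paste(class(x), collapse = "/"))
}

sts_from_z <- function(z, call) {
  if (is.null(rownames(z))) rownames(z) <- sprintf("row%d", seq_len(nrow(z)))
  all_missing <- rowSums(!is.na(z)) == 0L
  if (any(all_missing)) {
    warnf("excluding accession(s) with no observed trait: %s",
          paste(rownames(z)[all_missing], collapse = ", "))
    z <- z[!all_missing, , drop = FALSE]
  }
  if (nrow(z) == 0L) stopf("no accession has any observed trait")
  score <- rowMeans(z, na.rm = TRUE)
  ord <- order(-score, names(score))
  rk <- integer(length(score))
  rk[ord] <- seq_along(score)
  names(rk) <- names(score)
  structure(list(score = score, rank = rk, z = z, retention = NULL,
                 call = call),
            class = "sts")
}

#' @export
print.sts <- function(x, digits = 3, ...) {
  cat("Salt Tolerance Score (mean of column-Z-scored trait retentions)\n")
  cat(sprintf("  %d accessions, %d trait columns\n", nrow(x$z), ncol(x$z)))
  top <- names(sort(x$score, decreasing = TRUE))[seq_len(min(5, length(x$score)))]
  cat("  most tolerant: ",
      paste(sprintf("%s (%.*f)", top, digits, x$score[top]), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.sts <- function(object, ...) {
  s <- object$score
  structure(list(n = length(s), n_traits = ncol(object$z),
                 quantiles = stats::quantile(s),
                 top = utils::head(sort(s, decreasing = TRUE), 10),
                 bottom = utils::head(sort(s), 10)),
            class = "summary.sts")
}

#' @export
print.summary.sts <- function(x, ...) {
  cat(sprintf("STS over %d accessions (%d trait columns)\n", x$n, x$n_traits))
  print(round(x$quantiles, 3))
  cat("Top accessions:\n"); print(round(x$top, 3))
  cat("Bottom accessions:\n"); print(round(x$bottom, 3))
  invisible(x)
}

#' @export
#' @rdname sts
#' @param object,fit an `sts` fit.
coef.sts <- function(object, ...) object$score

#' @export
plot.sts <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::hist(x$score, breaks = "FD", main = "STS distribution",
                 xlab = "Salt Tolerance Score", col = "grey80")
  ord <- sort(x$score, decreasing = TRUE)
  graphics::plot(seq_along(ord), ord, type = "h", lwd = 2,
                 main = "Ranked accessions", xlab = "rank", ylab = "STS")
  invisible(x)
}

#' Select score extremes
#'
#' Returns the top and bottom `ceiling(q * n)` accessions by STS — the
#' operational definition of the tolerant and sensitive groups used for
#' classifier labels (default q = 0.20) and for the qRT-PCR validation panel
#' (q = 0.05, i.e. 5 + 5 accessions in a cohort of 100).
#'
#' @param fit an `sts` fit.
#' @param q tail fraction, in (0, 0.5); the two tails must not overlap.
#' @return List with character vectors `tolerant` and `sensitive`, most
#'   extreme first.
#' @export
select_extremes <- function(fit, q = 0.20) {
  if (!inherits(fit, "sts")) stopf("fit must be an sts object")
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 0.5)
    stopf("q must lie strictly between 0 and 0.5")
  n <- length(fit$score)
  k <- ceiling(q * n)
  if (2L * k > n) stopf("tails of %d would overlap in a cohort of %d", k, n)
  ord <- names(fit$score)[order(-fit$score, names(fit$score))]
  list(tolerant = ord[seq_len(k)], sensitive = rev(ord)[seq_len(k)])
}
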