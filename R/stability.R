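#' Bootstrap stability of the STS ranking
#'
#' How robust is an accession's Top-K position to perturbations of the trait
#' set? Each bootstrap iteration resamples the standardized trait columns
#' with replacement (same number of columns), recomputes the row-mean score
#' and the ranking, and records which accessions land in the Top K. The hit
#' rate per accession is the fraction of iterations in which it ranked
#' within the Top K. Resampling columns rather than accessions probes
#' sensitivity to the trait panel — which traits happened to be measured —
#' not to the cohort; an accession-resampling mode is available for
#' comparison (an accession's hit rate is then the fraction of iterations,
#' among those where it was drawn, in which it ranked within the Top K).
#'
#' Column z-scores are reused as drawn: z-scoring is idempotent per column,
#' so duplicated columns need no restandardization.
#'
#' @param fit an `sts` fit, or a numeric z-matrix (rows = accessions).
#' @param B bootstrap iterations (default 1000).
#' @param K ranking cutoff (default 20).
#' @param seed integer seed for reproducibility.
#' @param resample `"traits"` (default) or `"accessions"`.
#' @return Object of class `sts_bootstrap`: data frame `hits` (accession,
#'   hit_rate, sorted descending) plus settings.
#' @examples
#' z <- matrix(rnorm(60), 10, 6, dimnames = list(letters[1:10], NULL))
#' bootstrap_topk(sts(z), B = 100, K = 3, seed = 1)
#' @export
bootstrap_topk <- function(fit, B = 1000, K = 20, seed = NULL,
                           resample = c("traits", "accessions")) {
  z <- if (inherits(fit, "sts")) fit$z else as.matrix(fit)
  resample <- match.arg(resample)
  if (!is_count(B)) stopf("B must be a positive integer")
  n <- nrow(z)
  p <- ncol(z)
  if (p == 0L) stopf("no trait columns to resample")
  if (!is_count(K) || K > n) stopf("K must satisfy 1 <= K <= %d accessions", n)
  acc <- rownames(z)
  if (is.null(acc)) acc <- sprintf("row%d", seq_len(n))

  hits <- numeric(n)
  appearances <- numeric(n)
  with_seed(seed, {
    for (b in seq_len(B)) {
      if (resample == "traits") {
        zb <- z[, sample.int(p, p, replace = TRUE), drop = FALSE]
        rows <- seq_len(n)
      } else {
        rows <- sample.int(n, n, replace = TRUE)
        zb <- zscore_columns(z[rows, , drop = FALSE])
      }
      score <- rowMeans(zb, na.rm = TRUE)
      ord <- order(-score, acc[rows])
      top <- unique(rows[ord][seq_len(min(K, length(ord)))])
      hits[top] <- hits[top] + 1
      appearances[unique(rows)] <- appearances[unique(rows)] + 1
    }
  })
  denom <- if (resample == "traits") B else pmax(appearances, 1)
  out <- data.frame(accession = acc, hit_rate = hits / denom,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$hit_rate, out$accession), ]
  rownames(out) <- NULL
  structure(list(hits = out, B = as.integer(B), K = as.integer(K),
                 resample = resample, seed = seed),
            class = "sts_bootstrap")
}

#' @export
print.sts_bootstrap <- function(x, ...) {
  cat(sprintf("Top-%d hit rates over %d bootstrap iterations (%s resampled)\n",
              x$K, x$B, x$resample))
  print(utils::head(x$hits, 10))
  invisible(x)
}
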