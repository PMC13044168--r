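# Isolation Forest in base R.
#
# An isolation tree recursively splits a random feature at a random cut point
# between the observed min and max; anomalous points are isolated in few
# splits, so their expected path length across a forest of trees grown on
# random subsamples is short. The anomaly score follows the standard
# normalisation s(x) = 2^(-E[h(x)] / c(psi)), where c(psi) is the average
# path length of an unsuccessful BST search among psi points, so scores are
# comparable across subsample sizes: scores near 1 are anomalies, scores
# well below 0.5 are ordinary points.

# average path length of unsuccessful search in a BST of size n
avg_path_length <- function(n) {
  ifelse(n <= 1, 0, 2 * (log(n - 1) + 0.5772156649015329) - 2 * (n - 1) / n)
}

grow_itree <- function(x, depth, max_depth) {
  n <- nrow(x)
  if (n <= 1L || depth >= max_depth) {
    return(list(size = n))
  }
  spread <- apply(x, 2, function(v) max(v) - min(v))
  usable <- which(spread > 0)
  if (length(usable) == 0L) return(list(size = n))
  j <- if (length(usable) == 1L) usable else sample(usable, 1L)
  cut <- stats::runif(1, min(x[, j]), max(x[, j]))
  left <- x[, j] < cut
  list(feature = j, cut = cut,
       left = grow_itree(x[left, , drop = FALSE], depth + 1L, max_depth),
       right = grow_itree(x[!left, , drop = FALSE], depth + 1L, max_depth))
}

itree_path <- function(node, x, depth = 0) {
  if (is.null(node$feature)) return(depth + avg_path_length(node$size))
  if (x[node$feature] < node$cut) itree_path(node$left, x, depth + 1)
  else itree_path(node$right, x, depth + 1)
}

isolation_forest_scores <- function(x, n_trees = 100L, sample_size = 256L) {
  n <- nrow(x)
  psi <- min(sample_size, n)
  max_depth <- ceiling(log2(max(psi, 2)))
  paths <- matrix(0, n, n_trees)
  for (t in seq_len(n_trees)) {
    idx <- sample.int(n, psi)
    tree <- grow_itree(x[idx, , drop = FALSE], 0L, max_depth)
    paths[, t] <- apply(x, 1, function(row) itree_path(tree, row))
  }
  2^(-rowMeans(paths) / avg_path_length(psi))
}

#' Flag accessions with anomalous stress-response patterns
#'
#' Runs an Isolation Forest on the log2-retention (response-spectrum) matrix
#' and flags the most anomalous accessions — multi-trait response patterns
#' that deviate strongly from the population, candidate idiosyncratic
#' tolerance or sensitivity types. Missing cells are median-imputed per
#' column for this step only.
#'
#' @param m a `retention_matrix` (its `log2R` view is used) or a numeric
#'   matrix of response features.
#' @param contamination expected anomaly fraction in (0, 0.5);
#'   `ceiling(contamination * n)` accessions are flagged.
#' @param seed integer seed for the subsampling and split randomness.
#' @param n_trees trees in the forest.
#' @param sample_size subsample size per tree (capped at n).
#' @return Object of class `anomaly_report`: data frame `report` (accession,
#'   score, flag) sorted by descending anomaly score, plus settings.
#' @examples
#' m <- matrix(rnorm(200), 50, 4)
#' m[1, ] <- 10  # planted outlier
#' detect_anomalies(m, contamination = 0.02, seed = 1)
#' @export
detect_anomalies <- function(m, contamination = 0.05, seed = NULL,
                             n_trees = 100L, sample_size = 256L) {
  if (inherits(m, "retention_matrix")) m <- m$log2R
  m <- as.matrix(m)
  if (!is.numeric(contamination) || contamination <= 0 || contamination >= 0.5)
    stopf("contamination must lie strictly between 0 and 0.5")
  if (anyNA(m)) m <- impute_col_median(m)
  acc <- rownames(m)
  if (is.null(acc)) acc <- sprintf("row%d", seq_len(nrow(m)))
  scores <- with_seed(seed, isolation_forest_scores(m, n_trees, sample_size))
  k <- ceiling(contamination * nrow(m))
  ord <- order(-scores, acc)
  flag <- logical(nrow(m))
  flag[ord[seq_len(k)]] <- TRUE
  report <- data.frame(accession = acc, score = scores, flag = flag,
                       stringsAsFactors = FALSE)[ord, ]
  rownames(report) <- NULL
  structure(list(report = report, contamination = contamination,
                 n_trees = n_trees, seed = seed),
            class = "anomaly_report")
}

#' @export
print.anomaly_report <- function(x, ...) {
  cat(sprintf("Isolation Forest anomaly report (%d trees, contamination %.2f)\n",
              x$n_trees, x$contamination))
  print(utils::head(x$report, sum(x$report$flag)))
  invisible(x)
}
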