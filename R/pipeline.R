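#' Run the full screening pipeline
#'
#' End-to-end orchestration: germination traits -> retention matrix -> STS ->
#' bootstrap ranking stability -> PCA/K-means typing, correlation structure,
#' CCA, anomaly flagging -> random-forest classification of score extremes,
#' and (when a Ct table is supplied) delta-delta-Ct expression analysis.
#' One CSV is written per stage plus a JSON run manifest recording package
#' version, seed, settings and input hashes, so two runs with the same
#' inputs and seed produce byte-identical outputs.
#'
#' @param germination germination records (data frame or CSV path):
#'   accession, treatment, replicate, day, n_new, n_total.
#' @param biomass biomass table (data frame or CSV path): accession,
#'   treatment, replicate, fresh_g, dry_g. Optional.
#' @param ct_table Ct table (data frame or CSV path) for the expression
#'   stage. Optional.
#' @param out_dir directory for stage outputs; created if needed. `NULL`
#'   skips writing.
#' @param treatments control / stress labels, control first.
#' @param gp_day,vi_weight_basis trait settings, see [build_trait_table()].
#' @param extreme_q tail fraction defining classifier labels.
#' @param bootstrap_B,bootstrap_K bootstrap settings, see [bootstrap_topk()].
#' @param trees,folds classifier settings, see [classify_extremes()].
#' @param contamination anomaly fraction, see [detect_anomalies()].
#' @param seed integer master seed; every stochastic stage receives a seed
#'   derived from it.
#' @return Invisibly, a list with every stage result (`traits`, `retention`,
#'   `sts`, `screen`, `bootstrap`, `typing`, `correlations`, `cross_env`,
#'   `cca`, `anomalies`, `classifier`, `gini`, `permutation`, optionally
#'   `expression` and `expression_tests`, and `manifest`).
#' @export
run_pipeline <- function(germination, biomass = NULL, ct_table = NULL,
                         out_dir = NULL, treatments = c("CK", "NaCl150"),
                         gp_day = 3, vi_weight_basis = "fresh",
                         extreme_q = 0.20, bootstrap_B = 1000,
                         bootstrap_K = 20, trees = 500, folds = 5,
                         contamination = 0.05, seed = 1L) {
  germination <- read_table_arg(germination, .germ_cols, "germination")
  if (!is.null(biomass))
    biomass <- read_table_arg(biomass, .biomass_cols, "biomass")
  if (!is.null(ct_table))
    ct_table <- read_table_arg(ct_table, .ct_cols, "ct_table")
  present <- unique(germination$treatment)
  missing_tr <- setdiff(treatments, present)
  if (length(missing_tr) > 0L)
    stopf("germination input lacks treatment(s): %s",
          paste(missing_tr, collapse = ", "))
  # one derived seed per stochastic stage, all reproducible from `seed`
  stage_seed <- function(k) (as.integer(seed) * 7L + k * 1009L) %% .Machine$integer.max

  res <- list()
  res$traits <- build_trait_table(germination, biomass, gp_day = gp_day,
                                  vi_weight_basis = vi_weight_basis)
  res$retention <- build_retention_matrix(res$traits, treatments = treatments)
  res$sts <- sts(res$retention)
  res$screen <- trait_screen(res$traits, treatments = treatments)
  res$bootstrap <- bootstrap_topk(res$sts, B = bootstrap_B,
                                  K = min(bootstrap_K, length(res$sts$score)),
                                  seed = stage_seed(1L))
  res$typing <- pca_typing(res$sts, seed = stage_seed(2L))
  res$correlations <- trait_correlations(res$retention)
  res$cross_env <- cross_env_correlation(res$traits, treatments = treatments)

  wide <- function(tr) {
    d <- res$traits[res$traits$treatment == tr, , drop = FALSE]
    acc <- rownames(res$retention$R)
    trt <- colnames(res$retention$R)
    m <- matrix(NA_real_, length(acc), length(trt),
                dimnames = list(acc, trt))
    d <- d[d$accession %in% acc, , drop = FALSE]
    m[cbind(match(d$accession, acc), match(d$trait, trt))] <- d$value
    m
  }
  res$cca <- cca_consistency(impute_col_median(wide(treatments[1])),
                             impute_col_median(wide(treatments[2])))
  res$anomalies <- detect_anomalies(res$retention,
                                    contamination = contamination,
                                    seed = stage_seed(3L))
  extremes <- select_extremes(res$sts, q = extreme_q)
  res$classifier <- classify_extremes(res$sts, extremes, trees = trees,
                                      folds = folds, seed = stage_seed(4L))
  res$gini <- gini_importance(res$classifier)
  res$permutation <- permutation_importance(res$classifier, repeats = 10,
                                            seed = stage_seed(5L))
  if (!is.null(ct_table)) {
    res$expression <- ddct(ct_table, treatments = treatments)
    res$expression_tests <- expression_contrasts(res$expression,
                                                 treatments = treatments)
  }

  res$manifest <- list(
    package = "saltol",
    version = as.character(utils::packageVersion("saltol")),
    seed = as.integer(seed),
    settings = list(treatments = treatments, gp_day = gp_day,
                    vi_weight_basis = vi_weight_basis, extreme_q = extreme_q,
                    bootstrap_B = bootstrap_B, bootstrap_K = bootstrap_K,
                    trees = trees, folds = folds,
                    contamination = contamination),
    n_accessions = length(res$sts$score),
    input_hashes = list(
      germination = table_hash(germination),
      biomass = if (is.null(biomass)) NULL else table_hash(biomass),
      ct_table = if (is.null(ct_table)) NULL else table_hash(ct_table)))

  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  invisible(res)
}

read_table_arg <- function(x, cols, what) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stopf("%s file not found: %s", what, x)
    x <- utils::read.csv(x, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(x)) stopf("%s must be a data frame or CSV path", what)
  check_columns(x, cols, what)
  bad_row <- which(!stats::complete.cases(x[intersect(cols, names(x))]))
  if (length(bad_row) > 0L && what == "germination")
    stopf("%s: missing value(s) in row(s) %s", what,
          paste(utils::head(bad_row, 5), collapse = ", "))
  x
}

# order-invariant content hash of a table (djb2 over serialized cells)
table_hash <- function(df) {
  df <- df[do.call(order, df), , drop = FALSE]
  s <- paste(capture_rows(df), collapse = "\n")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

capture_rows <- function(df) {
  do.call(paste, c(lapply(df, function(col) {
    if (is.numeric(col)) formatC(col, digits = 12, format = "g") else as.character(col)
  }), sep = ","))
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)

  w(res$traits, "traits.csv")
  r <- res$retention
  w(data.frame(accession = rownames(r$R), r$R, check.names = FALSE),
    "retention.csv")
  w(data.frame(accession = names(res$sts$score), sts = res$sts$score,
               rank = res$sts$rank, row.names = NULL), "sts.csv")
  w(res$screen, "trait_screen.csv")
  w(res$bootstrap$hits, "bootstrap_topk.csv")
  w(res$typing$scores, "typing.csv")
  w(data.frame(trait = rownames(res$correlations), res$correlations,
               check.names = FALSE), "trait_correlations.csv")
  w(res$cross_env, "cross_env_correlation.csv")
  w(res$anomalies$report, "anomalies.csv")
  w(data.frame(accession = names(res$classifier$prob),
               label = as.character(res$classifier$labels),
               prob_tolerant = res$classifier$prob, row.names = NULL),
    "classifier_probabilities.csv")
  w(res$classifier$roc, "roc.csv")
  imp <- data.frame(trait = names(res$gini), gini = as.numeric(res$gini),
                    permutation = as.numeric(
                      res$permutation[names(res$gini)]), row.names = NULL)
  w(imp, "importance.csv")
  if (!is.null(res$expression)) {
    w(res$expression, "expression.csv")
    w(res$expression_tests, "expression_tests.csv")
  }
  jsonlite::write_json(res$manifest,
                       file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
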