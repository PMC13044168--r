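#' Configure a synthetic qRT-PCR panel
#'
#' Parameters for [simulate_ct_table()]. The default eight-gene panel mirrors
#' the structure of a germination-stage validation experiment: four ion
#' transport / homeostasis genes induced under salt stress (strongly in
#' tolerant accessions, weakly in sensitive ones), one core stress-response
#' gene, and three transcription factors down-regulated under stress, more so
#' in tolerant accessions.
#'
#' Stress shifts the target-gene Ct by `-log2(fold change)` for the
#' accession's class and the gene's category; the reference gene is
#' treatment-invariant by construction. Gaussian noise acts in cycle space.
#'
#' @param genes data frame with columns `gene` and `category`; categories must
#'   be among ion_transport, core_response, transcription_factor.
#' @param fold_change_tolerant,fold_change_sensitive named vectors of
#'   multiplicative expression changes under stress, one entry per category,
#'   all > 0. Intermediate-class accessions get the geometric mean of the two.
#' @param ct_noise_sd Gaussian noise of measured Ct values, in cycles.
#' @param reference_ct_mean mean Ct of the reference (housekeeping) gene.
#' @param target_ct_mean mean Ct of target genes under control conditions.
#' @param n_replicates biological replicates per accession and treatment.
#' @param rng_seed integer seed; `NULL` uses the global RNG.
#' @return An object of class `expression_config`.
#' @export
expression_config <- function(genes = data.frame(
                                gene = c("IT1", "IT2", "IT3", "IT4",
                                         "CR1", "TF1", "TF2", "TF3"),
                                category = c(rep("ion_transport", 4),
                                             "core_response",
                                             rep("transcription_factor", 3)),
                                stringsAsFactors = FALSE),
                              fold_change_tolerant = c(ion_transport = 3.0,
                                                       core_response = 2.5,
                                                       transcription_factor = 0.4),
                              fold_change_sensitive = c(ion_transport = 1.3,
                                                        core_response = 1.2,
                                                        transcription_factor = 0.8),
                              ct_noise_sd = 0.2,
                              reference_ct_mean = 20,
                              target_ct_mean = 24,
                              n_replicates = 3L,
                              rng_seed = NULL) {
  categories <- c("ion_transport", "core_response", "transcription_factor")
  check_columns(genes, c("gene", "category"), "genes")
  bad <- setdiff(unique(genes$category), categories)
  if (length(bad) > 0L)
    stopf("unknown gene category: %s", paste(bad, collapse = ", "))
  for (fc in list(fold_change_tolerant, fold_change_sensitive)) {
    if (!all(unique(genes$category) %in% names(fc)))
      stopf("fold changes must be named for every category present in genes")
    if (any(fc <= 0)) stopf("fold changes must be > 0")
  }
  if (ct_noise_sd < 0) stopf("ct_noise_sd must be >= 0")
  if (!is_count(n_replicates)) stopf("n_replicates must be a positive integer")

  structure(list(genes = genes,
                 fold_change_tolerant = fold_change_tolerant,
                 fold_change_sensitive = fold_change_sensitive,
                 ct_noise_sd = ct_noise_sd,
                 reference_ct_mean = reference_ct_mean,
                 target_ct_mean = target_ct_mean,
                 n_replicates = as.integer(n_replicates),
                 rng_seed = rng_seed),
            class = "expression_config")
}

#' Simulate a cycle-threshold (Ct) table for a validation panel
#'
#' Generates target and reference Ct values per accession, treatment,
#' replicate and gene. The control-condition target Ct is centred on
#' `target_ct_mean`; under stress it is shifted by `-log2(fold change)` so
#' that the delta-delta-Ct machinery downstream recovers the configured fold
#' changes exactly when `ct_noise_sd = 0`.
#'
#' @param config an [expression_config()].
#' @param truth the `truth` data frame of a [simulate_cohort()] result
#'   (accession, tau, class).
#' @param accessions accession labels to include; typically the score
#'   extremes, see [select_extremes()]. Default: all accessions in `truth`.
#' @param treatments control / stress labels, control first.
#' @return Data frame of class `ct_table` with columns accession, group
#'   (accession's tolerance class), treatment, replicate, gene, ct_target,
#'   ct_reference.
#' @export
simulate_ct_table <- function(config = expression_config(), truth,
                              accessions = truth$accession,
                              treatments = c("CK", "NaCl150")) {
  if (!inherits(config, "expression_config"))
    stopf("config must be built with expression_config()")
  check_columns(truth, c("accession", "class"), "truth")
  unknown <- setdiff(accessions, truth$accession)
  if (length(unknown) > 0L)
    stopf("accession(s) not present in truth: %s",
          paste(unknown, collapse = ", "))
  with_seed(config$rng_seed,
            simulate_ct_impl(config, truth, accessions, treatments))
}

simulate_ct_impl <- function(config, truth, accessions, treatments) {
  cls <- truth$class[match(accessions, truth$accession)]
  grid <- expand.grid(gene = config$genes$gene,
                      replicate = seq_len(config$n_replicates),
                      treatment = treatments,
                      accession = accessions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("accession", "treatment", "replicate", "gene")]
  grid$group <- cls[match(grid$accession, accessions)]
  cat_of <- config$genes$category[match(grid$gene, config$genes$gene)]

  fc <- ifelse(grid$group == "tolerant",
               config$fold_change_tolerant[cat_of],
               ifelse(grid$group == "sensitive",
                      config$fold_change_sensitive[cat_of],
                      sqrt(config$fold_change_tolerant[cat_of] *
                           config$fold_change_sensitive[cat_of])))
  stress <- grid$treatment == treatments[2]
  mu_target <- config$target_ct_mean - ifelse(stress, log2(fc), 0)

  n <- nrow(grid)
  sd <- config$ct_noise_sd
  grid$ct_target <- mu_target + if (sd > 0) rnorm(n, 0, sd) else 0
  grid$ct_reference <- config$reference_ct_mean +
    if (sd > 0) rnorm(n, 0, sd) else 0
  out <- grid[, .ct_cols]
  class(out) <- c("ct_table", "data.frame")
  out
}
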