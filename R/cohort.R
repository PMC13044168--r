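#' Configure a synthetic germination cohort
#'
#' Builds the parameter set for [simulate_cohort()]. The defaults emulate a
#' germination-stage salt-tolerance screen: 100 accessions scored daily for a
#' week under a control (CK, 0 mM NaCl) and a salt treatment (NaCl150, 150 mM
#' NaCl), three biological replicates of 50 seeds each, and a latent tolerance
#' gradient partitioned into tolerant / intermediate / sensitive classes.
#'
#' Each accession carries a latent retention multiplier \eqn{\tau \in (0, 1]}
#' drawn uniformly within its class range. Under salt stress the per-day
#' germination hazard and the biomass means are multiplied by \eqn{\tau}, so a
#' lower \eqn{\tau} means stronger suppression and the trait-retention ratios
#' downstream are monotone in \eqn{\tau} by construction.
#'
#' @param n_accessions number of accessions in the cohort.
#' @param n_replicates biological replicates per accession and treatment.
#' @param n_days daily observation points; must match `length(daily_hazard_ck)`.
#' @param seeds_per_unit seeds sown per replicate dish (N_t).
#' @param treatments labels for the control and stress arms, in that order.
#' @param class_proportions named probabilities for the tolerant, intermediate
#'   and sensitive classes; must sum to 1.
#' @param tolerance_range named list of `c(lo, hi)` tau ranges per class, each
#'   inside (0, 1].
#' @param daily_hazard_ck per-day conditional germination probabilities under
#'   CK, applied to the seeds still ungerminated that morning.
#' @param biomass_mean_ck named vector `c(fresh = , dry = )` of per-plant
#'   biomass means (g) under CK.
#' @param noise list with elements `count` and `biomass`. `count > 0` draws
#'   daily counts binomially (the natural sampling noise of a counting assay);
#'   `count = 0` switches to deterministic expected (fractional) counts, the
#'   noise-free limit used by parameter-recovery checks. `biomass` is the
#'   coefficient of variation of per-plant weights.
#' @param rng_seed integer seed; `NULL` uses (and advances) the global RNG.
#' @return An object of class `cohort_config`.
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_accessions = 100L,
                          n_replicates = 3L,
                          n_days = 7L,
                          seeds_per_unit = 50L,
                          treatments = c("CK", "NaCl150"),
                          class_proportions = c(tolerant = 0.25,
                                                intermediate = 0.50,
                                                sensitive = 0.25),
                          tolerance_range = list(tolerant = c(0.75, 0.95),
                                                 intermediate = c(0.50, 0.75),
                                                 sensitive = c(0.20, 0.50)),
                          daily_hazard_ck = c(0.02, 0.15, 0.35, 0.30,
                                              0.20, 0.10, 0.05),
                          biomass_mean_ck = c(fresh = 0.05, dry = 0.008),
                          noise = list(count = 1, biomass = 0.10),
                          rng_seed = NULL) {
  if (!is_count(n_accessions) || !is_count(n_replicates) || !is_count(n_days))
    stopf("n_accessions, n_replicates and n_days must be positive integers")
  if (!is_count(seeds_per_unit))
    stopf("seeds_per_unit must be a positive integer (got %s)",
          format(seeds_per_unit))
  if (length(treatments) != 2L || anyDuplicated(treatments))
    stopf("treatments must be two distinct labels (control first)")
  classes <- c("tolerant", "intermediate", "sensitive")
  if (!setequal(names(class_proportions), classes))
    stopf("class_proportions must be named tolerant/intermediate/sensitive")
  class_proportions <- class_proportions[classes]
  if (any(class_proportions < 0) || abs(sum(class_proportions) - 1) > 1e-8)
    stopf("class_proportions must be non-negative and sum to 1")
  if (!setequal(names(tolerance_range), classes))
    stopf("tolerance_range must be named tolerant/intermediate/sensitive")
  tolerance_range <- tolerance_range[classes]
  for (cl in classes) {
    rg <- tolerance_range[[cl]]
    if (length(rg) != 2L || any(rg <= 0) || any(rg > 1) || rg[1] > rg[2])
      stopf("tolerance_range$%s must be c(lo, hi) inside (0, 1]", cl)
  }
  if (length(daily_hazard_ck) != n_days)
    stopf("daily_hazard_ck must have length n_days = %d", n_days)
  if (any(daily_hazard_ck < 0) || any(daily_hazard_ck > 1))
    stopf("daily hazards must lie in [0, 1]")
  if (!all(c("fresh", "dry") %in% names(biomass_mean_ck)) ||
      any(biomass_mean_ck < 0))
    stopf("biomass_mean_ck must be c(fresh = , dry = ) with non-negative values")
  if (!is.list(noise) || !all(c("count", "biomass") %in% names(noise)) ||
      noise$count < 0 || noise$biomass < 0)
    stopf("noise must be list(count = , biomass = ) with non-negative values")

  structure(list(n_accessions = as.integer(n_accessions),
                 n_replicates = as.integer(n_replicates),
                 n_days = as.integer(n_days),
                 seeds_per_unit = as.integer(seeds_per_unit),
                 treatments = as.character(treatments),
                 class_proportions = class_proportions,
                 tolerance_range = tolerance_range,
                 daily_hazard_ck = as.numeric(daily_hazard_ck),
                 biomass_mean_ck = biomass_mean_ck,
                 noise = noise,
                 rng_seed = rng_seed),
            class = "cohort_config")
}

#' Simulate a germination cohort under control and salt stress
#'
#' Germination is a discrete-time hazard process: each day every still
#' ungerminated seed germinates independently with that day's hazard. Under
#' the stress arm the daily hazards and the per-plant biomass means are scaled
#' by the accession's latent tolerance multiplier tau. With `noise$count > 0`
#' daily counts are binomial draws on the remaining seeds; with `noise$count
#' = 0` they are the (fractional) expected counts, making the whole cohort a
#' deterministic, strictly monotone function of tau.
#'
#' @param config a [cohort_config()].
#' @return A list of class `salt_cohort` with components
#'   \describe{
#'     \item{germination}{long data frame: accession, treatment, replicate,
#'       day, n_new (newly germinated that day), n_total (seeds sown).}
#'     \item{biomass}{data frame: accession, treatment, replicate, fresh_g,
#'       dry_g — per-plant weights in grams.}
#'     \item{truth}{data frame: accession, tau, class — the latent ground
#'       truth, for parameter-recovery checks only.}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_accessions = 10, rng_seed = 1))
#' head(cohort$germination)
#' @export
simulate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config"))
    stopf("config must be built with cohort_config()")
  with_seed(config$rng_seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  n <- config$n_accessions
  acc <- sprintf("ACC%03d", seq_len(n))
  classes <- c("tolerant", "intermediate", "sensitive")

  cls <- sample(classes, n, replace = TRUE, prob = config$class_proportions)
  lo <- vapply(config$tolerance_range, `[`, numeric(1), 1L)[cls]
  hi <- vapply(config$tolerance_range, `[`, numeric(1), 2L)[cls]
  tau <- runif(n, lo, hi)
  truth <- data.frame(accession = acc, tau = tau, class = cls,
                      stringsAsFactors = FALSE)

  ctrl <- config$treatments[1]
  stress <- config$treatments[2]
  units <- expand.grid(replicate = seq_len(config$n_replicates),
                       treatment = c(ctrl, stress),
                       accession = acc,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  units <- units[, c("accession", "treatment", "replicate")]
  n_units <- nrow(units)
  unit_tau <- ifelse(units$treatment == stress,
                     tau[match(units$accession, acc)], 1)

  N <- config$seeds_per_unit
  stochastic <- config$noise$count > 0
  remaining <- rep(as.numeric(N), n_units)
  counts <- matrix(0, nrow = n_units, ncol = config$n_days)
  for (d in seq_len(config$n_days)) {
    p <- pmin(1, config$daily_hazard_ck[d] * unit_tau)
    g <- if (stochastic) rbinom(n_units, round(remaining), p) else remaining * p
    counts[, d] <- g
    remaining <- remaining - g
  }

  germination <- data.frame(
    accession = rep(units$accession, each = config$n_days),
    treatment = rep(units$treatment, each = config$n_days),
    replicate = rep(units$replicate, each = config$n_days),
    day = rep(seq_len(config$n_days), times = n_units),
    n_new = as.vector(t(counts)),
    n_total = N,
    stringsAsFactors = FALSE)

  cv <- config$noise$biomass
  fresh_mu <- config$biomass_mean_ck[["fresh"]] * unit_tau
  dry_mu <- config$biomass_mean_ck[["dry"]] * unit_tau
  if (cv > 0) {
    fresh <- pmax(rnorm(n_units, fresh_mu, cv * fresh_mu), 1e-6)
    dry <- pmax(rnorm(n_units, dry_mu, cv * dry_mu), 1e-7)
  } else {
    fresh <- fresh_mu
    dry <- dry_mu
  }
  dry <- pmin(dry, fresh) # dry weight can never exceed fresh weight
  biomass <- data.frame(units, fresh_g = fresh, dry_g = dry,
                        stringsAsFactors = FALSE)

  structure(list(germination = germination, biomass = biomass,
                 truth = truth, config = config),
            class = "salt_cohort")
}

#' @export
print.salt_cohort <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic germination cohort\n")
  cat(sprintf("  %d accessions x %s x %d replicates, %d days, %d seeds/dish\n",
              cfg$n_accessions, paste(cfg$treatments, collapse = " + "),
              cfg$n_replicates, cfg$n_days, cfg$seeds_per_unit))
  cat(sprintf("  classes: %s\n",
              paste(sprintf("%s %.0f%%", names(cfg$class_proportions),
                            100 * cfg$class_proportions), collapse = ", ")))
  invisible(x)
}

#' Write a simulated cohort to CSV files
#'
#' Writes `germination.csv`, `biomass.csv` and `truth.csv` (fixed column
#' layouts, see [simulate_cohort()]) into `dir`.
#'
#' @param cohort a `salt_cohort`.
#' @param dir output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "salt_cohort")) stopf("cohort must be a salt_cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("germination.csv", "biomass.csv", "truth.csv"))
  utils::write.csv(cohort$germination, paths[1], row.names = FALSE)
  utils::write.csv(cohort$biomass, paths[2], row.names = FALSE)
  utils::write.csv(cohort$truth, paths[3], row.names = FALSE)
  invisible(paths)
}
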