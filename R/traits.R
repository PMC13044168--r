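#' Germination traits from daily counts
#'
#' Trait formulas for a single experimental unit (one accession x treatment x
#' replicate dish). `obs` is a data frame with columns `day` (1-based,
#' strictly increasing), `n_new` (seeds newly germinated that day) and
#' `n_total` (seeds sown, constant within the unit).
#'
#' \describe{
#'   \item{`germination_rate`}{GR = 100 x (total germinated)/N_t, the final
#'     germination percentage.}
#'   \item{`germination_potential`}{GP = 100 x (germinated through day
#'     `gp_day`)/N_t, an early-window percentage capturing speed and
#'     uniformity. A `gp_day` past the last observation reduces to GR.}
#'   \item{`germination_index`}{GI = sum over days of G_i / D_i, the
#'     day-weighted count; larger values mean faster germination. Days are
#'     1-based so seeds germinating on day 1 carry weight 1.}
#'   \item{`vigor_index`}{VI = GI x W, with W the mean per-plant biomass (g,
#'     fresh or dry).}
#' }
#'
#' @param obs one-unit data frame (see above).
#' @param gp_day early census day for germination potential; default 3.
#' @param gi,w germination index and mean per-plant biomass for `vigor_index`.
#' @return A single numeric value (GR/GP in percent, GI in seeds/day, VI in
#'   GI x g).
#' @examples
#' obs <- data.frame(day = 1:3, n_new = c(2, 3, 5), n_total = 50)
#' germination_rate(obs)       # 20
#' germination_index(obs)      # 2/1 + 3/2 + 5/3
#' @export
germination_rate <- function(obs) {
  obs <- validate_obs_unit(obs)
  100 * sum(obs$n_new) / obs$n_total[1]
}

#' @rdname germination_rate
#' @export
germination_potential <- function(obs, gp_day = 3) {
  obs <- validate_obs_unit(obs)
  if (!is.numeric(gp_day) || length(gp_day) != 1L || gp_day < 1)
    stopf("gp_day must be a day >= 1")
  100 * sum(obs$n_new[obs$day <= gp_day]) / obs$n_total[1]
}

#' @rdname germination_rate
#' @export
germination_index <- function(obs) {
  obs <- validate_obs_unit(obs)
  sum(obs$n_new / obs$day)
}

#' @rdname germination_rate
#' @export
vigor_index <- function(gi, w) {
  if (any(gi < 0, na.rm = TRUE) || any(w < 0, na.rm = TRUE))
    stopf("vigor_index requires non-negative GI and biomass")
  gi * w
}

validate_obs_unit <- function(obs) {
  check_columns(obs, c("day", "n_new", "n_total"), "germination observations")
  if (nrow(obs) == 0L) stopf("no observation days")
  if (anyDuplicated(obs$day)) stopf("duplicate observation day within a unit")
  obs <- obs[order(obs$day), , drop = FALSE]
  if (any(obs$day < 1)) stopf("days must be 1-based")
  if (any(obs$n_new < 0)) stopf("negative germination count")
  nt <- unique(obs$n_total)
  if (length(nt) != 1L) stopf("n_total must be constant within a unit")
  if (nt <= 0) stopf("n_total must be positive")
  if (sum(obs$n_new) > nt + 1e-9)
    stopf("cumulative germinated count exceeds seeds sown")
  obs
}

#' Build the accession x treatment trait table
#'
#' Computes GR, GP, GI, VI and per-plant fresh/dry weight for every
#' experimental unit, then lays them out as replicate-suffixed traits
#' (`GI_1`, `GI_2`, ..., plus `GI_mean`) per accession and treatment — the
#' layout the retention matrix and all downstream multivariate analyses use.
#'
#' @param germination long data frame: accession, treatment, replicate, day,
#'   n_new, n_total (the generator's germination schema).
#' @param biomass data frame: accession, treatment, replicate, fresh_g, dry_g.
#'   Units missing biomass get `NA` vigor index and weights; the germination
#'   traits are still computed.
#' @param gp_day early census day for germination potential.
#' @param vi_weight_basis biomass basis of the vigor index, `"fresh"`
#'   (default) or `"dry"`.
#' @param replicate_suffix if `TRUE` (default) per-replicate traits are
#'   emitted alongside the replicate mean; if `FALSE` only the means.
#' @return A long data frame of class `trait_table` with columns accession,
#'   treatment, trait, value. Percent traits are on the 0-100 scale.
#' @export
build_trait_table <- function(germination, biomass = NULL, gp_day = 3,
                              vi_weight_basis = c("fresh", "dry"),
                              replicate_suffix = TRUE) {
  check_columns(germination, .germ_cols, "germination table")
  vi_weight_basis <- match.arg(vi_weight_basis)
  g <- germination
  if (any(g$n_new < 0)) stopf("negative germination count")
  if (any(g$day < 1)) stopf("days must be 1-based")

  key <- paste(g$accession, g$treatment, g$replicate, sep = "\r")
  if (anyDuplicated(paste(key, g$day, sep = "\r")))
    stopf("duplicate observation day within a unit")
  ukey <- unique(key)
  idx <- match(key, ukey)
  first <- match(ukey, key)

  nt <- g$n_total[first]
  total <- as.vector(rowsum(g$n_new, idx))
  if (any(total > nt + 1e-9))
    stopf("cumulative germinated count exceeds seeds sown")
  gr <- 100 * total / nt
  gp <- 100 * as.vector(rowsum(g$n_new * (g$day <= gp_day), idx)) / nt
  gi <- as.vector(rowsum(g$n_new / g$day, idx))

  units <- data.frame(accession = g$accession[first],
                      treatment = g$treatment[first],
                      replicate = g$replicate[first],
                      stringsAsFactors = FALSE)
  fresh <- dry <- rep(NA_real_, length(ukey))
  if (!is.null(biomass)) {
    check_columns(biomass, .biomass_cols, "biomass table")
    bkey <- paste(biomass$accession, biomass$treatment, biomass$replicate,
                  sep = "\r")
    m <- match(ukey, bkey)
    fresh <- biomass$fresh_g[m]
    dry <- biomass$dry_g[m]
    if (any(dry > fresh + 1e-12, na.rm = TRUE))
      stopf("dry weight exceeds fresh weight")
  }
  w <- if (vi_weight_basis == "fresh") fresh else dry
  vi <- vigor_index(gi, w)

  values <- cbind(GR = gr, GP = gp, GI = gi, VI = vi,
                  fresh_weight = fresh, dry_weight = dry)

  pieces <- list()
  if (replicate_suffix) {
    pieces$rep <- data.frame(
      accession = rep(units$accession, times = ncol(values)),
      treatment = rep(units$treatment, times = ncol(values)),
      trait = paste0(rep(colnames(values), each = nrow(values)), "_",
                     rep(units$replicate, times = ncol(values))),
      value = as.vector(values),
      stringsAsFactors = FALSE)
  }
  agg_key <- paste(units$accession, units$treatment, sep = "\r")
  uagg <- unique(agg_key)
  afirst <- match(uagg, agg_key)
  means <- apply(values, 2, function(v)
    as.vector(tapply(v, factor(agg_key, levels = uagg), mean)))
  pieces$mean <- data.frame(
    accession = rep(units$accession[afirst], times = ncol(values)),
    treatment = rep(units$treatment[afirst], times = ncol(values)),
    trait = paste0(rep(colnames(values), each = length(uagg)), "_mean"),
    value = as.vector(means),
    stringsAsFactors = FALSE)

  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out <- out[order(out$accession, out$treatment, out$trait), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("trait_table", "data.frame")
  out
}
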