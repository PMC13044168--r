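#' Trait retention under stress
#'
#' Retention R = Trait_stress / Trait_control strips baseline differences
#' among accessions: an accession germinating poorly even in water is not
#' penalised twice. Conventions for zero controls: both values zero gives
#' R = 1 (no change); a zero control with a positive stress value is
#' undefined and returned as `NA` rather than an infinite retention that
#' would dominate downstream z-scores.
#'
#' @param trait_ck,trait_salt non-negative trait values under control and
#'   stress (vectorised).
#' @return Retention ratio(s), `NA` where undefined.
#' @examples
#' retention(80, 40)  # 0.5
#' @export
retention <- function(trait_ck, trait_salt) {
  if (any(trait_ck < 0, na.rm = TRUE) || any(trait_salt < 0, na.rm = TRUE))
    stopf("trait values must be non-negative")
  r <- trait_salt / trait_ck
  both_zero <- !is.na(trait_ck) & !is.na(trait_salt) &
    trait_ck == 0 & trait_salt == 0
  r[both_zero] <- 1
  r[!is.na(trait_ck) & trait_ck == 0 & !both_zero] <- NA_real_
  r
}

#' Build the accession x trait retention matrix
#'
#' Pairs each trait column across the two treatments and fills one retention
#' cell per accession and trait, together with the log2 response-spectrum
#' view (`log2R`) and the relative decline rate (`RD = 1 - R`). Accessions
#' observed in only one treatment are dropped with a warning.
#'
#' @param traits a [build_trait_table()] result (long: accession, treatment,
#'   trait, value).
#' @param treatments control / stress labels, control first.
#' @return Object of class `retention_matrix`: list with matrices `R`,
#'   `log2R` (NA where R = 0), `RD`, logical `mask` of missing cells, and the
#'   treatment labels. Rows are accessions, columns traits.
#' @export
build_retention_matrix <- function(traits, treatments = c("CK", "NaCl150")) {
  check_columns(traits, c("accession", "treatment", "trait", "value"),
                "trait table")
  present <- unique(traits$treatment)
  missing_tr <- setdiff(treatments, present)
  if (length(missing_tr) > 0L)
    stopf("trait table lacks treatment(s): %s",
          paste(missing_tr, collapse = ", "))

  wide <- function(tr) {
    d <- traits[traits$treatment == tr, , drop = FALSE]
    acc <- sort(unique(d$accession))
    trt <- sort(unique(d$trait))
    m <- matrix(NA_real_, length(acc), length(trt),
                dimnames = list(acc, trt))
    m[cbind(match(d$accession, acc), match(d$trait, trt))] <- d$value
    m
  }
  ck <- wide(treatments[1])
  salt <- wide(treatments[2])

  acc <- intersect(rownames(ck), rownames(salt))
  dropped <- setdiff(union(rownames(ck), rownames(salt)), acc)
  if (length(dropped) > 0L)
    warnf("excluding accession(s) present in one treatment only: %s",
          paste(dropped, collapse = ", "))
  cols <- intersect(colnames(ck), colnames(salt))
  ck <- ck[acc, cols, drop = FALSE]
  salt <- salt[acc, cols, drop = FALSE]

  R <- retention(ck, salt)
  dim(R) <- dim(ck)
  dimnames(R) <- dimnames(ck)
  log2R <- ifelse(!is.na(R) & R > 0, log2(R), NA_real_)
  structure(list(R = R, log2R = log2R, RD = 1 - R, mask = is.na(R),
                 treatments = treatments),
            class = "retention_matrix")
}

#' @export
print.retention_matrix <- function(x, ...) {
  cat(sprintf("Retention matrix: %d accessions x %d traits (%s / %s)\n",
              nrow(x$R), ncol(x$R), x$treatments[2], x$treatments[1]))
  cat(sprintf("  missing cells: %d\n", sum(x$mask)))
  cat(sprintf("  median R by trait: %s\n",
              paste(sprintf("%s %.2f", colnames(x$R),
                            apply(x$R, 2, stats::median, na.rm = TRUE))[
                              seq_len(min(4, ncol(x$R)))],
                    collapse = ", ")))
  invisible(x)
}

#' Column-wise Z-score standardization
#'
#' Centres and scales each column to mean 0 and sample standard deviation 1
#' (denominator n - 1). Constant columns are mapped to all zeros rather than
#' NaN; missing cells stay missing and are excluded from the column
#' statistics.
#'
#' @param m a `retention_matrix` (its `R` view is used) or a numeric matrix.
#' @return Numeric matrix of z-scores with the input's dimnames.
#' @export
zscore_columns <- function(m) {
  if (inherits(m, "retention_matrix")) m <- m$R
  m <- as.matrix(m)
  if (nrow(m) < 2L) stopf("z-scores need at least 2 rows (sd is undefined)")
  mu <- colMeans(m, na.rm = TRUE)
  sdv <- apply(m, 2, stats::sd, na.rm = TRUE)
  z <- sweep(m, 2, mu, "-")
  nonconst <- !is.na(sdv) & sdv > 0
  z[, nonconst] <- sweep(z[, nonconst, drop = FALSE], 2, sdv[nonconst], "/")
  z[, !nonconst] <- 0
  z[is.na(m)] <- NA_real_
  z
}
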