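#' Paired and Welch two-sample contrasts with effect sizes
#'
#' Thin wrappers around [stats::t.test()] that add the effect sizes used
#' throughout the screening workflow and degrade gracefully on
#' zero-variance input (where the t statistic is undefined).
#'
#' `paired_t` runs the one-sample t-test on within-accession differences
#' (x - y) and reports Cohen's d_z = mean(d)/sd(d). When every difference is
#' identical the result is flagged `degenerate` with p = 1 if the common
#' difference is 0 (identical arms) and p = 0 otherwise (a constant,
#' unambiguous shift).
#'
#' `welch_t` runs the unequal-variance t-test with Welch-Satterthwaite
#' degrees of freedom (fractional) and reports
#' d = (mean(a) - mean(b)) / sqrt((s_a^2 + s_b^2)/2).
#'
#' @param x,y paired measurements, aligned by accession (x is typically the
#'   control arm).
#' @param a,b independent samples for the Welch contrast.
#' @return List of class `contrast_test`: `statistic`, `df`, `p.value`,
#'   `effect_size`, `mean_diff`, `n` (per arm), `degenerate`, `method`.
#' @examples
#' paired_t(c(5, 7, 9), c(4, 5, 6))
#' welch_t(c(1, 2, 3), c(2, 3, 4))
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stopf("paired arms must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) stopf("need at least 2 complete pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    return(contrast_result(statistic = NA_real_, df = length(d) - 1,
                           p.value = if (all(d == 0)) 1 else 0,
                           effect_size = 0, mean_diff = mean(d),
                           n = length(d), degenerate = TRUE,
                           method = "paired t"))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  contrast_result(statistic = unname(tt$statistic),
                  df = unname(tt$parameter), p.value = tt$p.value,
                  effect_size = mean(d) / stats::sd(d),
                  mean_diff = mean(d), n = length(d),
                  degenerate = FALSE, method = "paired t")
}

#' @rdname paired_t
#' @export
welch_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) stopf("each arm needs >= 2 values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    same <- a[1] == b[1]
    return(contrast_result(statistic = NA_real_,
                           df = length(a) + length(b) - 2,
                           p.value = if (same) 1 else 0,
                           effect_size = if (same) 0 else Inf * sign(a[1] - b[1]),
                           mean_diff = mean(a) - mean(b),
                           n = c(length(a), length(b)),
                           degenerate = TRUE, method = "Welch t"))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  contrast_result(statistic = unname(tt$statistic),
                  df = unname(tt$parameter), p.value = tt$p.value,
                  effect_size = (mean(a) - mean(b)) /
                    sqrt((stats::var(a) + stats::var(b)) / 2),
                  mean_diff = mean(a) - mean(b),
                  n = c(length(a), length(b)),
                  degenerate = FALSE, method = "Welch t")
}

contrast_result <- function(...) structure(list(...), class = "contrast_test")

#' @export
print.contrast_test <- function(x, ...) {
  cat(sprintf("%s: t = %s, df = %.2f, p = %.3g, effect size = %.3f%s\n",
              x$method,
              if (is.na(x$statistic)) "NA" else sprintf("%.3f", x$statistic),
              x$df, x$p.value, x$effect_size,
              if (x$degenerate) " (degenerate: zero variance)" else ""))
  invisible(x)
}

#' Effect-size / significance screen over all traits
#'
#' For every trait, a paired t-test of control versus stress values across
#' accessions (each accession contributing one pair of replicate-mean
#' values), with Cohen's d_z. Traits are ranked by |d_z|, then by
#' significance, reproducing the "high effect - high significance" screening
#' view in which germination index and vigor index typically lead.
#'
#' @param traits a [build_trait_table()] result.
#' @param treatments control / stress labels, control first.
#' @param adjust if `TRUE`, add Benjamini-Hochberg adjusted q-values
#'   (off by default; the screen itself applies no multiplicity correction).
#' @return Data frame: trait, n, mean_ck, mean_stress, t, df, p, d_z (and q
#'   when requested), ranked by (|d_z|, -log10 p) descending.
#' @export
trait_screen <- function(traits, treatments = c("CK", "NaCl150"),
                         adjust = FALSE) {
  check_columns(traits, c("accession", "treatment", "trait", "value"),
                "trait table")
  trts <- sort(unique(traits$trait))
  rows <- lapply(trts, function(tr) {
    d <- traits[traits$trait == tr, , drop = FALSE]
    dck <- d[d$treatment == treatments[1], , drop = FALSE]
    dsa <- d[d$treatment == treatments[2], , drop = FALSE]
    if (nrow(dck) == 0L || nrow(dsa) == 0L) {
      warnf("trait %s missing a treatment; skipped", tr)
      return(NULL)
    }
    common <- intersect(dck$accession, dsa$accession)
    ck <- dck$value[match(common, dck$accession)]
    sa <- dsa$value[match(common, dsa$accession)]
    ok <- stats::complete.cases(ck, sa)
    if (sum(ok) < 3L) return(NULL)
    tt <- paired_t(ck[ok], sa[ok])
    data.frame(trait = tr, n = sum(ok),
               mean_ck = mean(ck[ok]), mean_stress = mean(sa[ok]),
               t = tt$statistic, df = tt$df, p = tt$p.value,
               d_z = tt$effect_size, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) stopf("no testable trait found")
  if (adjust) out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(-abs(out$d_z), out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
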