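#' Relative expression by the delta-delta-Ct method
#'
#' Computes, per sample and gene, \eqn{\Delta Ct = Ct_{target} -
#' Ct_{reference}}, \eqn{\Delta\Delta Ct = \Delta Ct - } (calibrator), and
#' the relative expression \eqn{2^{-\Delta\Delta Ct}}. The calibrator is the
#' arithmetic mean control-condition \eqn{\Delta Ct} of the same accession
#' and gene, so control replicates scatter around 1 and their geometric mean
#' is exactly 1 by construction. Technical replicates (duplicate rows for
#' the same accession x treatment x replicate x gene) are averaged in Ct
#' space before \eqn{\Delta Ct}.
#'
#' @param ct a Ct table (accession, group, treatment, replicate, gene,
#'   ct_target, ct_reference), e.g. from [simulate_ct_table()]. Samples with
#'   a missing reference Ct are dropped with a warning.
#' @param treatments control / stress labels, control first; the control arm
#'   is the calibrator condition.
#' @return Data frame of class `expression_result`: the sample key plus
#'   `delta_ct`, `delta_delta_ct`, `rel_expr` and `log2_rel` (= -ddCt).
#' @examples
#' ct <- data.frame(accession = "A", group = "tolerant",
#'                  treatment = rep(c("CK", "NaCl150"), each = 3),
#'                  replicate = rep(1:3, 2), gene = "IT1",
#'                  ct_target = c(24, 24, 24, 22, 22, 22), ct_reference = 20)
#' ddct(ct)$rel_expr  # stress replicates at 4-fold induction
#' @export
ddct <- function(ct, treatments = c("CK", "NaCl150")) {
  check_columns(ct, setdiff(.ct_cols, "group"), "Ct table")
  if (!"group" %in% names(ct)) ct$group <- NA_character_
  drop <- is.na(ct$ct_reference) | is.na(ct$ct_target)
  if (any(drop)) {
    warnf("dropping %d sample(s) with missing Ct values", sum(drop))
    ct <- ct[!drop, , drop = FALSE]
  }
  if (nrow(ct) == 0L) stopf("no usable Ct rows")

  # average technical replicates in Ct space
  kcols <- c("accession", "group", "treatment", "replicate", "gene")
  key <- do.call(paste, c(ct[kcols], sep = "\r"))
  if (anyDuplicated(key)) {
    first <- match(unique(key), key)
    idx <- match(key, unique(key))
    agg <- ct[first, kcols]
    agg$ct_target <- as.vector(rowsum(ct$ct_target, idx) / tabulate(idx))
    agg$ct_reference <- as.vector(rowsum(ct$ct_reference, idx) / tabulate(idx))
    ct <- agg
  }

  out <- ct[, kcols]
  out$delta_ct <- ct$ct_target - ct$ct_reference

  is_ck <- out$treatment == treatments[1]
  if (!any(is_ck)) stopf("no samples in the calibrator condition %s",
                         treatments[1])
  cal_key <- paste(out$accession, out$gene, sep = "\r")
  ck_mean <- tapply(out$delta_ct[is_ck], cal_key[is_ck], mean)
  cal <- ck_mean[cal_key]
  no_cal <- is.na(cal)
  if (any(no_cal)) {
    warnf("dropping %d sample(s) without a control calibrator", sum(no_cal))
    out <- out[!no_cal, , drop = FALSE]
    cal <- cal[!no_cal]
  }
  out$delta_delta_ct <- out$delta_ct - as.numeric(cal)
  out$rel_expr <- 2^(-out$delta_delta_ct)
  out$log2_rel <- -out$delta_delta_ct
  rownames(out) <- NULL
  class(out) <- c("expression_result", "data.frame")
  out
}

#' Expression contrasts for the validation panel
#'
#' Per gene, two families of contrasts on log2 relative expression
#' (accession means over replicates as experimental units):
#' \describe{
#'   \item{stress response}{paired t-test of control vs stress within
#'     accessions — did the treatment shift expression at all?}
#'   \item{group difference}{Welch t-test of tolerant vs sensitive
#'     accessions within each treatment — do the score extremes differ?}
#' }
#' Contrasts with fewer than 2 accessions per arm are skipped with a
#' warning. Log2 relative expression equals \eqn{-\Delta\Delta Ct}, so the
#' tests are identical on either scale.
#'
#' @param expr an [ddct()] result with a `group` column containing
#'   `tolerant` / `sensitive`.
#' @param treatments control / stress labels, control first.
#' @return Data frame: gene, contrast (`"CK_vs_stress"` or
#'   `"tolerant_vs_sensitive:<treatment>"`), group (for the paired family),
#'   t, df, p, effect_size, n.
#' @export
expression_contrasts <- function(expr, treatments = c("CK", "NaCl150")) {
  check_columns(expr, c("accession", "group", "treatment", "gene",
                        "log2_rel"), "expression result")
  acc_means <- stats::aggregate(
    log2_rel ~ accession + group + treatment + gene, data = expr, FUN = mean)

  rows <- list()
  for (g in unique(acc_means$gene)) {
    d <- acc_means[acc_means$gene == g, , drop = FALSE]

    ck <- d[d$treatment == treatments[1], , drop = FALSE]
    sa <- d[d$treatment == treatments[2], , drop = FALSE]
    common <- intersect(ck$accession, sa$accession)
    if (length(common) >= 2L) {
      tt <- paired_t(ck$log2_rel[match(common, ck$accession)],
                     sa$log2_rel[match(common, sa$accession)])
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, contrast = "CK_vs_stress", group = "all",
        t = tt$statistic, df = tt$df, p = tt$p.value,
        effect_size = tt$effect_size, n = tt$n[1],
        stringsAsFactors = FALSE)
    }

    for (tr in treatments) {
      dt <- d[d$treatment == tr, , drop = FALSE]
      tol <- dt$log2_rel[dt$group == "tolerant"]
      sen <- dt$log2_rel[dt$group == "sensitive"]
      if (length(tol) < 2L || length(sen) < 2L) {
        warnf("gene %s, treatment %s: a group has < 2 accessions; skipped",
              g, tr)
        next
      }
      tt <- welch_t(tol, sen)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, contrast = paste0("tolerant_vs_sensitive:", tr),
        group = tr, t = tt$statistic, df = tt$df, p = tt$p.value,
        effect_size = tt$effect_size, n = min(tt$n),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
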