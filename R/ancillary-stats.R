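tmt_columns <- function(quant) {
  ko <- grep("^ko_", names(quant), value = TRUE)
  wt <- grep("^wt_", names(quant), value = TRUE)
  if (length(ko) < 2L || length(wt) < 2L)
    rs_schema_error("protein quant", "need >= 2 ko_* and >= 2 wt_* columns")
  list(ko = ko, wt = wt)
}

#' Median-center KO/WT log2 ratios
#'
#' Subtracts a per-block constant from the KO channels so that each block's
#' median KO-WT log2 ratio is exactly 0 (the standard centering applied to
#' TMT reporter ratios before testing). Idempotent.
#'
#' @param quant Data.frame with `protein_id`, `ko_*` and `wt_*` log2-intensity
#'   columns, optionally a `block` column (e.g. cell line).
#' @return The table with centered KO channels.
#' @export
median_center_ratios <- function(quant) {
  cols <- tmt_columns(quant)
  block <- if ("block" %in% names(quant)) quant$block else rep("all", nrow(quant))
  if (nrow(quant) == 0L)
    rs_validation_error("median_center_ratios: empty block")
  for (b in unique(block)) {
    idx <- which(block == b)
    if (length(idx) == 0L)
      rs_validation_error("median_center_ratios: empty block")
    ratio <- rowMeans(quant[idx, cols$ko, drop = FALSE]) -
      rowMeans(quant[idx, cols$wt, drop = FALSE])
    m <- median(ratio)
    quant[idx, cols$ko] <- quant[idx, cols$ko, drop = FALSE] - m
  }
  quant
}

#' Enriched-interactor filter for TMT proteomics
#'
#' Per-protein two-sample Student's t-test (equal variance by default; Welch
#' via `var_equal = FALSE`) of KO against WT log2 intensities. A protein is
#' significant when its mean KO-WT log2 ratio reaches `log2(fc_threshold)`
#' (inclusive, one-directional: enrichment means enhanced interaction in KO)
#' and its p-value is strictly below `p_threshold`. Proteins with zero
#' variance in both groups get an undefined p-value, are flagged `degenerate`
#' and are never significant.
#'
#' @param quant Median-centered quant table (see [median_center_ratios()]).
#' @param fc_threshold Fold-change threshold (default 1.5).
#' @param p_threshold P-value threshold (default 0.075, strict `<`).
#' @param var_equal Use the pooled-variance Student's t-test (default TRUE).
#' @return Data.frame `protein_id`, `mean_log2_ratio`, `p_value`,
#'   `significant`, `degenerate`.
#' @export
test_enriched_interactors <- function(quant, fc_threshold = 1.5,
                                      p_threshold = 0.075, var_equal = TRUE) {
  cols <- tmt_columns(quant)
  n <- nrow(quant)
  ratio <- rowMeans(quant[, cols$ko, drop = FALSE]) -
    rowMeans(quant[, cols$wt, drop = FALSE])
  pval <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ko <- as.numeric(quant[i, cols$ko])
    wt <- as.numeric(quant[i, cols$wt])
    pval[i] <- tryCatch(
      t.test(ko, wt, var.equal = var_equal)$p.value,
      error = function(e) NA_real_)
  }
  data.frame(
    protein_id = quant$protein_id,
    mean_log2_ratio = ratio,
    p_value = pval,
    significant = !is.na(pval) & ratio >= log2(fc_threshold) &
      pval < p_threshold,
    degenerate = is.na(pval),
    stringsAsFactors = FALSE
  )
}

#' Overlap of significant sets between two experiments
#'
#' @param ids_a,ids_b Character vectors of significant ids.
#' @return List `n_a`, `n_b`, `n_overlap`, `overlap` (the shared ids).
#' @export
overlap_significant <- function(ids_a, ids_b) {
  ov <- sort(intersect(ids_a, ids_b))
  list(n_a = length(unique(ids_a)), n_b = length(unique(ids_b)),
       n_overlap = length(ov), overlap = ov)
}

#' Differential-expression threshold filter
#'
#' Classifies genes with `padj < padj_threshold` and `log2fc` strictly beyond
#' `lfc_threshold` as up- or down-regulated (both inequalities strict, as
#' conventionally printed: FDR-adjusted P < 0.01 and |log2FC| > 0.5).
#'
#' @param de_table DE data.frame.
#' @param padj_threshold Adjusted-p cut (default 0.01).
#' @param lfc_threshold Absolute log2FC cut (default 0.5).
#' @return List `up`, `down` (gene id vectors), `n_up`, `n_down`.
#' @export
de_filter <- function(de_table, padj_threshold = 0.01, lfc_threshold = 0.5) {
  ok <- !is.na(de_table$padj) & !is.na(de_table$log2fc)
  up <- de_table$gene_id[ok & de_table$padj < padj_threshold &
                           de_table$log2fc > lfc_threshold]
  down <- de_table$gene_id[ok & de_table$padj < padj_threshold &
                             de_table$log2fc < -lfc_threshold]
  list(up = up, down = down, n_up = length(up), n_down = length(down))
}

#' Per-miRNA log2 RPM fold changes
#'
#' RPM-normalizes each condition (pseudocount 1 on the numerator for
#' zero-count robustness), computes `log2(KO / WT)` per miRNA and returns the
#' table ranked by fold change.
#'
#' @param counts_wt,counts_ko Data.frames with `mirna_id` and `count`.
#' @param pseudocount Added to each count before normalization (default 1).
#' @return Data.frame `mirna_id`, `rpm_wt`, `rpm_ko`, `log2fc`, sorted by
#'   decreasing `log2fc`.
#' @export
mirna_differential <- function(counts_wt, counts_ko, pseudocount = 1) {
  ids <- sort(union(counts_wt$mirna_id, counts_ko$mirna_id))
  cw <- counts_wt$count[match(ids, counts_wt$mirna_id)]
  ck <- counts_ko$count[match(ids, counts_ko$mirna_id)]
  cw[is.na(cw)] <- 0; ck[is.na(ck)] <- 0
  lw <- sum(cw); lk <- sum(ck)
  if (lw <= 0 || lk <= 0)
    rs_validation_error("mirna_differential: each condition needs nonzero total counts")
  rpm_wt <- (cw + pseudocount) / lw * 1e6
  rpm_ko <- (ck + pseudocount) / lk * 1e6
  out <- data.frame(mirna_id = ids, rpm_wt = rpm_wt, rpm_ko = rpm_ko,
                    log2fc = log2(rpm_ko / rpm_wt), stringsAsFactors = FALSE)
  out[order(-out$log2fc, out$mirna_id), , drop = FALSE]
}

#' Fit Malthusian (exponential) growth
#'
#' Least-squares fit of `ln(count)` against time: `N(t) = N0 * exp(k t)`,
#' with doubling time `ln(2) / k`. With noiseless exponential input the fit is
#' exact.
#'
#' @param times Numeric times (days), >= 3 points.
#' @param counts Positive counts, same length.
#' @return List of class `"growth_fit"`: `n0`, `rate` (k, per day),
#'   `doubling_time` (days; `NA` with `k_positive = FALSE` when k <= 0),
#'   `r_squared`.
#' @export
fit_malthusian_growth <- function(times, counts) {
  if (length(times) != length(counts) || length(times) < 3L)
    rs_validation_error("fit_malthusian_growth: need >= 3 matching timepoints")
  if (any(!is.finite(counts)) || any(counts <= 0))
    rs_validation_error("fit_malthusian_growth: counts must be positive")
  fit <- lm(log(counts) ~ times)
  k <- unname(coef(fit)[2])
  structure(list(
    n0 = exp(unname(coef(fit)[1])),
    rate = k,
    doubling_time = if (k > 0) log(2) / k else NA_real_,
    k_positive = k > 0,
    # suppressed: summary.lm warns on noiseless (perfect-fit) input, which is
    # a legitimate case here
    r_squared = suppressWarnings(summary(fit)$r.squared)
  ), class = "growth_fit")
}
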