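#' Expression floor filter
#'
#' Keeps genes passing the expression floor used before differential analysis:
#' with a count matrix, at least `min_count` reads in at least `min_samples`
#' samples; without one (proxy mode), `base_mean >= min_count` on the DE
#' table.
#'
#' @param de_table DE data.frame (`gene_id`, `base_mean`, ...).
#' @param min_count Count floor (default 10).
#' @param min_samples Minimum samples meeting the floor (default 3).
#' @param counts Optional matrix of per-sample counts with genes as rownames.
#' @return Character vector of expressed gene ids.
#' @export
filter_expressed <- function(de_table, min_count = 10, min_samples = 3,
                             counts = NULL) {
  if (!is.null(counts)) {
    keep <- rowSums(counts >= min_count) >= min_samples
    return(rownames(counts)[keep])
  }
  de_table$gene_id[de_table$base_mean >= min_count]
}

#' Per-gene site counts from annotated clusters or planted truth
#'
#' @param annotated_clusters Output of [assign_clusters()].
#' @return Data.frame `gene_id`, `n_sites`, `total_reads`.
#' @export
gene_site_counts <- function(annotated_clusters) {
  keep <- !is.na(annotated_clusters$gene_id)
  cl <- annotated_clusters[keep, , drop = FALSE]
  if (nrow(cl) == 0L)
    return(data.frame(gene_id = character(0), n_sites = integer(0),
                      total_reads = integer(0), stringsAsFactors = FALSE))
  reads <- if ("read_count" %in% names(cl)) cl$read_count else rep(1L, nrow(cl))
  n <- tapply(rep(1L, nrow(cl)), cl$gene_id, sum)
  r <- tapply(reads, cl$gene_id, sum)
  data.frame(gene_id = names(n), n_sites = as.integer(n),
             total_reads = as.integer(r), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' @rdname gene_site_counts
#' @param truth A `synthetic_truth`; uses the planted AGO site table, with
#'   seed-match status taken from the planted motifs.
#' @return For `truth_gene_profiles()`: a list with `site_counts` and
#'   `seed_matches` data.frames ready for [build_profiles()].
#' @export
truth_gene_profiles <- function(truth) {
  tab <- truth$ago_sites
  n <- tapply(rep(1L, nrow(tab)), tab$gene_id, sum)
  sm <- tapply(!is.na(tab$seed_motif), tab$gene_id, sum)
  list(
    site_counts = data.frame(gene_id = names(n), n_sites = as.integer(n),
                             total_reads = NA_integer_,
                             stringsAsFactors = FALSE, row.names = NULL),
    seed_matches = data.frame(gene_id = names(sm),
                              n_seed_matched_sites = as.integer(sm),
                              seed_matched = as.integer(sm) > 0L,
                              stringsAsFactors = FALSE, row.names = NULL)
  )
}

#' Build per-gene target profiles
#'
#' Joins site counts, seed-match status and the DE table into one profile per
#' gene and computes AGO occupancy percentiles. Occupancy is operationalized
#' as the number of binding sites per gene (`weight_by_reads = TRUE` ranks by
#' total cluster read count instead). Percentiles are computed over
#' seed-matched bound expressed genes only, descending (percentile 1 = most
#' bound); ties rank the lexicographically smaller gene id worse, stably.
#' Gene classes: `non_target` (expressed, zero sites — the reference group),
#' `excluded` (bound but failing the seed filter), `below_floor` (failing the
#' expression floor), and seed-matched targets, which [bin_targets()] labels.
#' Genes with sites but absent from the DE table are dropped with a message.
#'
#' @param site_counts Data.frame `gene_id`, `n_sites` (see
#'   [gene_site_counts()]).
#' @param seed_matches Data.frame `gene_id`, `seed_matched` (see
#'   [aggregate_seed_matches()]).
#' @param de_table DE data.frame.
#' @param expressed Character vector of expressed genes; default
#'   [filter_expressed()] proxy mode.
#' @param weight_by_reads Rank occupancy by read count rather than site count.
#' @return Data.frame of class `"gene_profiles"`: `gene_id`, `n_sites`,
#'   `n_seed_matched_sites`, `seed_matched`, `occupancy_percentile`,
#'   `bin_label`, `log2fc`, `padj`, `base_mean`.
#' @export
build_profiles <- function(site_counts, seed_matches, de_table,
                           expressed = NULL, weight_by_reads = FALSE) {
  if (is.null(expressed)) expressed <- filter_expressed(de_table)
  orphans <- setdiff(site_counts$gene_id, de_table$gene_id)
  if (length(orphans))
    message(sprintf(
      "build_profiles: %d bound gene(s) absent from the DE table, excluded",
      length(orphans)))
  df <- de_table[, c("gene_id", "log2fc", "padj", "base_mean")]
  i <- match(df$gene_id, site_counts$gene_id)
  df$n_sites <- ifelse(is.na(i), 0L, site_counts$n_sites[i])
  df$total_reads <- ifelse(is.na(i), 0L,
                           if ("total_reads" %in% names(site_counts))
                             site_counts$total_reads[i] else NA_integer_)
  j <- match(df$gene_id, seed_matches$gene_id)
  df$n_seed_matched_sites <- ifelse(is.na(j), 0L,
                                    seed_matches$n_seed_matched_sites[j])
  df$seed_matched <- !is.na(j) & seed_matches$seed_matched[j]
  df$expressed <- df$gene_id %in% expressed

  df$occupancy_percentile <- NA_real_
  eligible <- which(df$expressed & df$n_sites > 0L & df$seed_matched)
  if (length(eligible)) {
    key <- if (weight_by_reads) df$total_reads[eligible] else df$n_sites[eligible]
    ord <- order(-key, -xtfrm(df$gene_id[eligible]))
    pct <- numeric(length(eligible))
    pct[ord] <- 100 * seq_along(eligible) / length(eligible)
    df$occupancy_percentile[eligible] <- pct
  }
  df$bin_label <- ifelse(!df$expressed, "below_floor",
                  ifelse(df$n_sites == 0L, "non_target",
                  ifelse(!df$seed_matched, "excluded", "unbinned")))
  out <- df[, c("gene_id", "n_sites", "n_seed_matched_sites", "seed_matched",
                "occupancy_percentile", "bin_label", "log2fc", "padj",
                "base_mean", "total_reads")]
  class(out) <- c("gene_profiles", "data.frame")
  out
}

#' Bin seed-matched targets by occupancy percentile
#'
#' Default bins reproduce the target ranking of the cumulative-distribution
#' analysis literally: percentiles in (5, 20] and (25, 100]; genes in (0, 5]
#' and (20, 25] stay `"unbinned"`. Bins are half-open on the left, closed on
#' the right.
#'
#' @param profiles A [build_profiles()] data.frame.
#' @param bins Named list of `c(lo, hi)` percentile pairs.
#' @return The profiles with `bin_label` set for binned targets.
#' @export
bin_targets <- function(profiles, bins = list(top_5_20 = c(5, 20),
                                              mid_25_100 = c(25, 100))) {
  for (nm in names(bins)) {
    lo <- bins[[nm]][1]; hi <- bins[[nm]][2]
    hit <- !is.na(profiles$occupancy_percentile) &
      profiles$bin_label %in% c("unbinned", names(bins)) &
      profiles$occupancy_percentile > lo & profiles$occupancy_percentile <= hi
    profiles$bin_label[hit] <- nm
  }
  profiles
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes the supremum distance between the two empirical CDFs directly,
#' with the p-value from the exact two-sample distribution
#' ([stats::psmirnov], tie-aware) when the smaller sample has fewer than 30
#' observations, and from the asymptotic Kolmogorov tail series otherwise.
#'
#' @param x,y Numeric samples, each non-empty.
#' @param exact Force (`TRUE`/`FALSE`) or auto-select (`NULL`) the exact
#'   p-value.
#' @return List with `statistic` (D), `p_value`, `n_x`, `n_y`.
#' @export
ks_two_sample <- function(x, y, exact = NULL) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1L || length(y) < 1L)
    rs_validation_error("ks_two_sample: both samples must be non-empty")
  n.x <- length(x); n.y <- length(y)
  w <- c(x, y)
  ord <- order(w)
  z <- cumsum(ifelse(ord <= n.x, 1 / n.x, -1 / n.y))
  ws <- w[ord]
  keep <- c(diff(ws) != 0, TRUE)
  D <- max(abs(z[keep]))
  if (is.null(exact)) exact <- min(n.x, n.y) < 30L
  p <- if (exact) {
    stats::psmirnov(D, sizes = c(n.x, n.y), z = w, two.sided = TRUE,
                    lower.tail = FALSE)
  } else {
    t <- sqrt(n.x * n.y / (n.x + n.y)) * D
    k <- seq_len(100)
    min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))))
  }
  list(statistic = D, p_value = p, n_x = n.x, n_y = n.y)
}

#' Compare target-bin log2FC distributions against non-targets
#'
#' The core cumulative-distribution analysis: for each occupancy bin, the log2
#' fold changes of its genes are compared with those of non-targets (expressed
#' genes with no binding site) by a two-sided two-sample KS test; the median
#' shift (bin median minus non-target median) quantifies the repression, with
#' negative shifts meaning the bin is downregulated relative to non-targets.
#'
#' @param profiles A binned [build_profiles()] data.frame.
#' @param group_labels Bin labels to compare (default: all bin labels present
#'   other than the bookkeeping classes).
#' @param reference_label Reference class (default `"non_target"`).
#' @return A data.frame with one row per comparison (`group_label`, `n_group`,
#'   `n_reference`, `ks_D`, `p_value`, `median_shift`), with the ECDF curves
#'   of every group attached as attribute `"curves"`.
#' @export
compare_ecdfs <- function(profiles, group_labels = NULL,
                          reference_label = "non_target") {
  ref <- profiles$log2fc[profiles$bin_label == reference_label]
  if (length(ref) == 0L)
    rs_validation_error("compare_ecdfs: no reference group (non-targets empty)")
  if (is.null(group_labels)) {
    group_labels <- setdiff(unique(profiles$bin_label),
                            c(reference_label, "excluded", "below_floor",
                              "unbinned"))
    group_labels <- sort(group_labels)
  }
  rows <- list()
  curves <- list(data.frame(group = reference_label, x = sort(ref),
                            F = seq_along(ref) / length(ref)))
  for (g in group_labels) {
    lfc <- profiles$log2fc[profiles$bin_label == g]
    if (length(lfc) == 0L) {
      warning(sprintf("compare_ecdfs: bin '%s' is empty, skipped", g))
      next
    }
    ks <- ks_two_sample(lfc, ref)
    rows[[g]] <- data.frame(
      group_label = g, n_group = length(lfc), n_reference = length(ref),
      ks_D = ks$statistic, p_value = ks$p_value,
      median_shift = median(lfc) - median(ref),
      stringsAsFactors = FALSE)
    curves[[g]] <- data.frame(group = g, x = sort(lfc),
                              F = seq_along(lfc) / length(lfc))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(group_label = character(0), n_group = integer(0),
                      n_reference = integer(0), ks_D = numeric(0),
                      p_value = numeric(0), median_shift = numeric(0))
  attr(out, "curves") <- do.call(rbind, c(curves, list(make.row.names = FALSE)))
  out
}
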