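#' Quantify AGO/FAM120A site overlap and co-binding
#'
#' Counts how many AGO binding sites are intersected by at least
#' `min_overlap_nt` nt of a FAM site on the same strand (site-level overlap,
#' the primary readout), alongside a nucleotide-level Jaccard index of the two
#' merged site sets, and derives gene-level co-binding sets from the sites'
#' gene assignments: `cobound` (genes bound by both), `a_only`, `b_only`.
#'
#' @param sites_a,sites_b Site or cluster data.frames (`chrom`, `start`,
#'   `end`, `strand`, optionally `gene_id`); A is the AGO side.
#' @param min_overlap_nt Minimum shared nucleotides (default 1).
#' @param same_strand Require matching strands (default TRUE).
#' @return A list of class `"cobinding_summary"`: `n_sites_a`, `n_sites_b`,
#'   `n_a_overlapped`, `site_overlap_fraction`, `nucleotide_jaccard`,
#'   `cobound_genes`, `a_only_genes`, `b_only_genes`.
#' @export
compute_site_overlap <- function(sites_a, sites_b, min_overlap_nt = 1L,
                                 same_strand = TRUE) {
  if (is.null(sites_a) || nrow(sites_a) == 0L)
    rs_validation_error("compute_site_overlap: empty site set A (fraction undefined)")
  gr_a <- as_granges0(sites_a$chrom, sites_a$start, sites_a$end, sites_a$strand)
  gr_b <- if (is.null(sites_b) || nrow(sites_b) == 0L)
    GenomicRanges::GRanges() else
    as_granges0(sites_b$chrom, sites_b$start, sites_b$end, sites_b$strand)
  hits <- GenomicRanges::findOverlaps(gr_a, gr_b,
                                      minoverlap = as.integer(min_overlap_nt),
                                      ignore.strand = !same_strand)
  n_over <- length(unique(S4Vectors::queryHits(hits)))

  red_a <- GenomicRanges::reduce(gr_a, ignore.strand = !same_strand)
  red_b <- GenomicRanges::reduce(gr_b, ignore.strand = !same_strand)
  inter <- sum(GenomicRanges::width(GenomicRanges::intersect(
    red_a, red_b, ignore.strand = !same_strand)))
  uni <- sum(GenomicRanges::width(GenomicRanges::union(
    red_a, red_b, ignore.strand = !same_strand)))

  genes_a <- if ("gene_id" %in% names(sites_a))
    unique(sites_a$gene_id[!is.na(sites_a$gene_id)]) else character(0)
  genes_b <- if (!is.null(sites_b) && "gene_id" %in% names(sites_b))
    unique(sites_b$gene_id[!is.na(sites_b$gene_id)]) else character(0)

  structure(list(
    n_sites_a = nrow(sites_a),
    n_sites_b = if (is.null(sites_b)) 0L else nrow(sites_b),
    n_a_overlapped = n_over,
    site_overlap_fraction = n_over / nrow(sites_a),
    nucleotide_jaccard = if (uni > 0) inter / uni else 0,
    cobound_genes = sort(intersect(genes_a, genes_b)),
    a_only_genes = sort(setdiff(genes_a, genes_b)),
    b_only_genes = sort(setdiff(genes_b, genes_a))
  ), class = "cobinding_summary")
}

#' Estimate site overlap from called clusters at footprint scale
#'
#' Called cluster intervals mark the conversion-dominant region around the
#' crosslink, which is narrower than the protein footprint; intersecting the
#' raw runs therefore underestimates binding-site overlap. This re-estimator
#' reconstructs a footprint-scale interval around each cluster's mode location
#' (`footprint` nt, centred) before computing the overlap summary, so two
#' clusters whose crosslinks sit within one footprint of each other count as
#' overlapping sites.
#'
#' @param clusters_a,clusters_b Cluster data.frames (A is the AGO side).
#' @param footprint Reconstructed site width in nt (default 24, the simulated
#'   footprint).
#' @param same_strand Require matching strands (default TRUE).
#' @return A [compute_site_overlap()] summary.
#' @export
estimate_site_overlap_from_clusters <- function(clusters_a, clusters_b,
                                                footprint = 24L,
                                                same_strand = TRUE) {
  pad <- function(cl) {
    half <- as.integer(footprint) %/% 2L
    out <- cl
    out$start <- pmax(0L, cl$mode_location - half)
    out$end <- cl$mode_location + (as.integer(footprint) - half)
    out
  }
  compute_site_overlap(pad(clusters_a), pad(clusters_b),
                       same_strand = same_strand)
}

#' Stabilization analysis of co-bound targets
#'
#' Splits co-bound genes by AGO binding preference (occupancy = AGO site
#' count) at the top `split_percentile` percent versus the rest, then compares
#' the log2FC distribution of each co-bound bin, of all co-bound genes, and of
#' AGO-only targets against non-targets (KS test and median shift). Genes
#' bound only by the competitor are removed from the reference. A co-bound bin
#' is flagged `stabilized` when its absolute median shift is smaller than the
#' AGO-only targets' — i.e. co-binding attenuates the repression seen on
#' AGO-only targets. A degenerate split (all co-bound genes at identical
#' occupancy) collapses to the single `cobound_all` bin with a warning.
#'
#' @param summary A [compute_site_overlap()] result.
#' @param profiles A [build_profiles()] data.frame (for occupancy, log2FC and
#'   the non-target reference).
#' @param split_percentile Top-percent cut on AGO occupancy (default 25).
#' @return Data.frame with columns `group_label`, `n_group`, `n_reference`,
#'   `ks_D`, `p_value`, `median_shift`, `stabilized`.
#' @export
stabilization_analysis <- function(summary, profiles, split_percentile = 25) {
  stopifnot(inherits(summary, "cobinding_summary"))
  cobound <- intersect(summary$cobound_genes, profiles$gene_id)
  cobound <- cobound[cobound %in%
                       profiles$gene_id[profiles$bin_label != "below_floor"]]
  if (length(cobound) == 0L)
    rs_validation_error("stabilization_analysis: empty co-bound gene set")
  ref_genes <- profiles$gene_id[profiles$bin_label == "non_target"]
  ref_genes <- setdiff(ref_genes, summary$b_only_genes)
  if (length(ref_genes) == 0L)
    rs_validation_error("stabilization_analysis: no non-target reference genes")
  lfc_of <- function(genes) profiles$log2fc[match(genes, profiles$gene_id)]
  ref <- lfc_of(ref_genes)

  occ <- profiles$n_sites[match(cobound, profiles$gene_id)]
  groups <- list(cobound_all = cobound)
  if (length(unique(occ)) == 1L) {
    warning("stabilization_analysis: degenerate occupancy split (all co-bound genes tied); using a single bin")
  } else {
    ord <- order(-occ, cobound)
    n_high <- max(1L, as.integer(round(length(cobound) * split_percentile / 100)))
    groups$cobound_high <- cobound[ord[seq_len(n_high)]]
    groups$cobound_low <- cobound[ord[-seq_len(n_high)]]
  }
  a_only <- intersect(summary$a_only_genes, profiles$gene_id)
  a_only <- a_only[a_only %in%
                     profiles$gene_id[profiles$bin_label != "below_floor"]]
  groups$a_only <- a_only

  a_shift <- if (length(a_only)) median(lfc_of(a_only)) - median(ref) else NA_real_
  rows <- lapply(names(groups), function(nm) {
    genes <- groups[[nm]]
    if (length(genes) == 0L) return(NULL)
    lfc <- lfc_of(genes)
    ks <- ks_two_sample(lfc, ref)
    shift <- median(lfc) - median(ref)
    data.frame(group_label = nm, n_group = length(genes),
               n_reference = length(ref), ks_D = ks$statistic,
               p_value = ks$p_value, median_shift = shift,
               stabilized = if (startsWith(nm, "cobound") && !is.na(a_shift))
                 abs(shift) < abs(a_shift) else NA,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
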