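#' One replicate of the truth-level RNAi recovery study
#'
#' Plants binding sites and expression changes on an existing transcriptome
#' and runs the occupancy-ranking / seed-filter / ECDF analysis directly on
#' the planted truth (site counts and seed flags), bypassing read simulation
#' and cluster calling. This isolates the statistical analysis: what it
#' recovers is the planted repression and stabilization, with the cluster
#' caller benchmarked separately against the same truth. The expression floor
#' is not applied here, so the target / non-target composition is exactly as
#' planted.
#'
#' @param tx A [generate_transcriptome()] result (reused across replicates;
#'   per-replicate randomness comes from `config$genome_seed`).
#' @param config A [sim_config()]; vary `genome_seed` per replicate.
#' @param bins Occupancy bins (see [bin_targets()]).
#' @param split_percentile Co-binding split for [stabilization_analysis()].
#' @return List: `truth`, `de`, `profiles` (binned), `comparisons`
#'   (bins vs non-targets), `stabilization` (co-bound analysis, `NULL` when
#'   there are no co-bound genes).
#' @export
rnai_recovery_run <- function(tx, config,
                              bins = list(top_5_20 = c(5, 20),
                                          mid_25_100 = c(25, 100)),
                              split_percentile = 25) {
  truth <- plant_binding_sites(tx$models, tx$genome, config)
  de <- simulate_expression_changes(truth, config)
  tp <- truth_gene_profiles(truth)
  profiles <- build_profiles(tp$site_counts, tp$seed_matches, de,
                             expressed = de$gene_id)
  profiles <- bin_targets(profiles, bins)
  comparisons <- compare_ecdfs(profiles)

  stabilization <- NULL
  if (length(truth$cobound_genes)) {
    summ <- structure(list(
      n_sites_a = nrow(truth$ago_sites), n_sites_b = nrow(truth$fam_sites),
      n_a_overlapped = sum(truth$ago_sites$overlapped),
      site_overlap_fraction = mean(truth$ago_sites$overlapped),
      nucleotide_jaccard = NA_real_,
      cobound_genes = truth$cobound_genes,
      a_only_genes = truth$ago_only_genes,
      b_only_genes = setdiff(unique(truth$fam_sites$gene_id),
                             unique(truth$ago_sites$gene_id))
    ), class = "cobinding_summary")
    stabilization <- stabilization_analysis(summ, profiles, split_percentile)
  }
  list(truth = truth, de = de, profiles = profiles,
       comparisons = comparisons, stabilization = stabilization)
}

#' Planted median shift of a profile group
#'
#' The truth-derived expectation the ECDF analysis should recover: the median
#' planted log2FC of the genes in a bin minus the median planted log2FC of
#' the reference group (0 for non-targets by construction).
#'
#' @param profiles Binned profiles from [rnai_recovery_run()].
#' @param de The matching DE table carrying `true_log2fc`.
#' @param group_label Bin label (e.g. `"top_5_20"`).
#' @param reference_label Reference class (default `"non_target"`).
#' @return The planted median shift (numeric scalar).
#' @export
planted_median_shift <- function(profiles, de, group_label,
                                 reference_label = "non_target") {
  tl <- de$true_log2fc[match(profiles$gene_id, de$gene_id)]
  grp <- tl[profiles$bin_label == group_label]
  ref <- tl[profiles$bin_label == reference_label]
  if (length(grp) == 0L || length(ref) == 0L)
    rs_validation_error("planted_median_shift: empty group")
  median(grp) - median(ref)
}

#' Planted median shift of a co-binding gene set
#'
#' @param genes Gene ids of the group (e.g. a co-bound bin).
#' @param de DE table with `true_log2fc`.
#' @param reference_genes Gene ids of the reference (non-targets).
#' @return The planted median shift.
#' @export
planted_set_shift <- function(genes, de, reference_genes) {
  grp <- de$true_log2fc[de$gene_id %in% genes]
  ref <- de$true_log2fc[de$gene_id %in% reference_genes]
  if (length(grp) == 0L || length(ref) == 0L)
    rs_validation_error("planted_set_shift: empty group")
  median(grp) - median(ref)
}

#' Benchmark the cluster caller against planted sites
#'
#' Matches called clusters to planted sites by the PAR-CLIP convention: a call
#' is a true positive when its `mode_location` falls inside a planted site
#' interval on the same strand. Precision is the matched fraction of calls;
#' recall the recovered fraction of planted sites.
#'
#' @param clusters [call_clusters()] output.
#' @param sites Planted site data.frame (`chrom`, `start`, `end`, `strand`).
#' @return List `precision`, `recall`, `n_calls`, `n_sites`, `n_matched_calls`,
#'   `n_recovered_sites`.
#' @export
benchmark_cluster_calls <- function(clusters, sites) {
  n_calls <- nrow(clusters); n_sites <- nrow(sites)
  if (n_calls == 0L)
    return(list(precision = NA_real_, recall = 0, n_calls = 0L,
                n_sites = n_sites, n_matched_calls = 0L,
                n_recovered_sites = 0L))
  mode_gr <- as_granges0(clusters$chrom, clusters$mode_location,
                         clusters$mode_location + 1L, clusters$strand)
  site_gr <- as_granges0(sites$chrom, sites$start, sites$end, sites$strand)
  hits <- GenomicRanges::findOverlaps(mode_gr, site_gr)
  matched_calls <- length(unique(S4Vectors::queryHits(hits)))
  recovered <- length(unique(S4Vectors::subjectHits(hits)))
  list(precision = matched_calls / n_calls, recall = recovered / n_sites,
       n_calls = n_calls, n_sites = n_sites,
       n_matched_calls = matched_calls, n_recovered_sites = recovered)
}
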