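sites_df <- function(start, end, strand = "+", gene = NA, chrom = "chr1") {
  n <- max(length(start), length(end), length(strand))
  data.frame(chrom = rep_len(chrom, n), start = rep_len(start, n),
             end = rep_len(end, n), strand = rep_len(strand, n),
             gene_id = rep_len(gene, n), stringsAsFactors = FALSE)
}

test_that("site overlap follows the 1 nt same-strand rule", {
  a <- sites_df(100L, 120L)
  b <- sites_df(119L, 140L)
  expect_equal(compute_site_overlap(a, b)$site_overlap_fraction, 1)
  expect_equal(compute_site_overlap(a, sites_df(120L, 140L))$site_overlap_fraction, 0)
  expect_equal(compute_site_overlap(a, b, min_overlap_nt = 2)$site_overlap_fraction, 0)
  b_minus <- sites_df(100L, 120L, "-")
  expect_equal(compute_site_overlap(a, b_minus)$site_overlap_fraction, 0)
  expect_equal(compute_site_overlap(a, b_minus,
                                    same_strand = FALSE)$site_overlap_fraction, 1)
  expect_error(compute_site_overlap(a[0, ], b),
               class = "riscshift_validation_error")
})

test_that("overlap of a site set with itself is exactly one", {
  s <- fix_truth$ago_sites
  self <- compute_site_overlap(s, s)
  expect_equal(self$site_overlap_fraction, 1)
  expect_equal(self$nucleotide_jaccard, 1)
})

test_that("overlap counts match a brute-force pair oracle", {
  set.seed(21)
  a <- sites_df(start <- sample(0:2000, 60, replace = TRUE), start + 24L,
                sample(c("+", "-"), 60, replace = TRUE))
  b <- sites_df(start2 <- sample(0:2000, 60, replace = TRUE), start2 + 24L,
                sample(c("+", "-"), 60, replace = TRUE))
  got <- compute_site_overlap(a, b)
  pairs_ab <- outer(seq_len(60), seq_len(60), Vectorize(function(i, j)
    a$strand[i] == b$strand[j] && a$start[i] < b$end[j] && b$start[j] < a$end[i]))
  expect_equal(got$n_a_overlapped, sum(rowSums(pairs_ab) > 0))
  # the same pair set seen from B: symmetric consistency
  swapped <- compute_site_overlap(b, a)
  expect_equal(swapped$n_a_overlapped, sum(colSums(pairs_ab) > 0))
})

test_that("planted truth overlap and gene sets are recovered exactly", {
  got <- compute_site_overlap(fix_truth$ago_sites, fix_truth$fam_sites)
  expect_equal(got$site_overlap_fraction,
               round(fix_cfg$site_overlap_fraction * fix_cfg$n_ago_sites) /
                 fix_cfg$n_ago_sites)
  expect_setequal(got$cobound_genes, fix_truth$cobound_genes)
  expect_setequal(got$a_only_genes, fix_truth$ago_only_genes)
  expect_true(length(intersect(got$cobound_genes, got$a_only_genes)) == 0)
  expect_true(length(intersect(got$cobound_genes, got$b_only_genes)) == 0)
})

stab_config <- function(gamma, seed) {
  sim_config(n_genes = 700, genome_seed = seed, n_ago_sites = 300,
             n_fam_sites = 300, n_target_genes = 250,
             site_overlap_fraction = 0.65, repression_beta = 0.5,
             stabilization_gamma = gamma, lfc_noise_sd = 0.2,
             seed_match_fraction = 1)
}

test_that("full protection and no protection are both recovered", {
  tx <- generate_transcriptome(stab_config(1, 1))
  run1 <- rnai_recovery_run(tx, stab_config(1, 401))
  st1 <- run1$stabilization
  cob <- st1$median_shift[st1$group_label %in% c("cobound_all", "cobound_high",
                                                 "cobound_low")]
  expect_true(all(abs(cob) < 0.1))
  a_shift <- st1$median_shift[st1$group_label == "a_only"]
  want <- planted_set_shift(run1$truth$ago_only_genes, run1$de,
                            run1$truth$nontarget_genes)
  expect_lt(abs(a_shift - want), 0.1)
  expect_true(all(st1$stabilized[st1$group_label == "cobound_all"]))

  run0 <- rnai_recovery_run(tx, stab_config(0, 402))
  st0 <- run0$stabilization
  expect_lt(abs(st0$median_shift[st0$group_label == "cobound_all"] -
                  st0$median_shift[st0$group_label == "a_only"]), 0.1)
})

test_that("stabilization flag has power under partial protection", {
  tx <- generate_transcriptome(stab_config(0.8, 1))
  flagged <- logical(15)
  for (s in seq_along(flagged)) {
    run <- rnai_recovery_run(tx, stab_config(0.8, 500 + s))
    st <- run$stabilization
    flagged[s] <- isTRUE(st$stabilized[st$group_label == "cobound_all"])
    if (s == 1) expect_gte(length(run$truth$cobound_genes), 150)
  }
  expect_gte(mean(flagged), 0.95)
})

test_that("degenerate occupancy split warns and collapses to one bin", {
  genes <- sprintf("g%03d", 1:60)
  de <- data.frame(gene_id = genes, base_mean = 100, log2fc = rnorm(60, 0, 0.1),
                   pvalue = 0.5, padj = 0.5)
  sc <- data.frame(gene_id = genes[1:20], n_sites = 2L, total_reads = 1L)
  sm <- data.frame(gene_id = genes[1:20], n_seed_matched_sites = 1L,
                   seed_matched = TRUE)
  p <- bin_targets(build_profiles(sc, sm, de, expressed = genes))
  summ <- structure(list(
    n_sites_a = 20L, n_sites_b = 10L, n_a_overlapped = 10L,
    site_overlap_fraction = 0.5, nucleotide_jaccard = NA_real_,
    cobound_genes = genes[1:10], a_only_genes = genes[11:20],
    b_only_genes = character(0)), class = "cobinding_summary")
  expect_warning(st <- stabilization_analysis(summ, p), "degenerate")
  expect_setequal(st$group_label, c("cobound_all", "a_only"))

  empty <- summ; empty$cobound_genes <- character(0)
  expect_error(stabilization_analysis(empty, p),
               class = "riscshift_validation_error")
})
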