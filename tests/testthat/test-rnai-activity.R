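test_that("expression floor applies in counts and proxy modes", {
  counts <- rbind(g1 = c(12, 11, 10, 0), g2 = c(12, 11, 0, 0))
  de <- data.frame(gene_id = c("g1", "g2"), base_mean = c(100, 100))
  expect_equal(filter_expressed(de, counts = counts), "g1")
  de2 <- data.frame(gene_id = c("g1", "g2"), base_mean = c(9.9, 10))
  expect_equal(filter_expressed(de2), "g2")
})

profiles_fixture <- function(n_targets = 100, n_nontargets = 50,
                             n_sites = NULL) {
  if (is.null(n_sites)) n_sites <- seq_len(n_targets)
  genes <- sprintf("g%04d", seq_len(n_targets + n_nontargets))
  tg <- genes[seq_len(n_targets)]
  de <- data.frame(gene_id = genes, base_mean = 100,
                   log2fc = 0, pvalue = 0.5, padj = 0.5,
                   stringsAsFactors = FALSE)
  sc <- data.frame(gene_id = tg, n_sites = n_sites, total_reads = n_sites * 10L)
  sm <- data.frame(gene_id = tg, n_seed_matched_sites = 1L, seed_matched = TRUE)
  build_profiles(sc, sm, de, expressed = genes)
}

test_that("occupancy percentiles are descending ranks over seed-matched targets", {
  p <- profiles_fixture(100, 50)
  tp <- p[!is.na(p$occupancy_percentile), ]
  expect_equal(sort(tp$occupancy_percentile), as.numeric(1:100))
  # most-bound gene (100 sites) holds percentile 1
  expect_equal(tp$occupancy_percentile[which.max(tp$n_sites)], 1)
  # ties: the lexicographically smaller gene id ranks worse (larger percentile)
  pt <- profiles_fixture(4, 10, n_sites = c(5L, 5L, 2L, 1L))
  tied <- pt[pt$n_sites == 5L, ]
  expect_gt(tied$occupancy_percentile[tied$gene_id == "g0001"],
            tied$occupancy_percentile[tied$gene_id == "g0002"])
})

test_that("gene classes and bins partition the DE table", {
  genes <- c("t1", "t2", "noseed", "nt", "low")
  de <- data.frame(gene_id = genes, base_mean = c(100, 100, 100, 100, 5),
                   log2fc = 0, pvalue = 0.5, padj = 0.5)
  sc <- data.frame(gene_id = c("t1", "t2", "noseed", "ghost"),
                   n_sites = c(3L, 1L, 2L, 1L), total_reads = 1L)
  sm <- data.frame(gene_id = c("t1", "t2"), n_seed_matched_sites = 1L,
                   seed_matched = TRUE)
  expect_message(p <- build_profiles(sc, sm, de), "absent from the DE table")
  expect_equal(p$bin_label[p$gene_id == "nt"], "non_target")
  expect_equal(p$bin_label[p$gene_id == "noseed"], "excluded")
  expect_equal(p$bin_label[p$gene_id == "low"], "below_floor")
  expect_false("ghost" %in% p$gene_id)
  p <- bin_targets(p)
  expect_setequal(p$gene_id,
                  de$gene_id)  # every DE gene classified exactly once
  expect_true(all(p$bin_label %in% c("top_5_20", "mid_25_100", "unbinned",
                                     "non_target", "excluded", "below_floor")))
})

test_that("percentile bins reproduce the 5-20 / 25-100 ranking convention", {
  p <- bin_targets(profiles_fixture(100, 50))
  tp <- p[!is.na(p$occupancy_percentile), ]
  expect_equal(sum(tp$bin_label == "top_5_20"), 15L)
  expect_setequal(tp$occupancy_percentile[tp$bin_label == "top_5_20"], 6:20)
  expect_setequal(tp$occupancy_percentile[tp$bin_label == "mid_25_100"], 26:100)
  expect_equal(tp$bin_label[tp$occupancy_percentile == 3], "unbinned")
  all_in <- bin_targets(profiles_fixture(100, 50),
                        bins = list(all_targets = c(0, 100)))
  expect_equal(sum(all_in$bin_label == "all_targets"), 100L)
})

test_that("KS statistic matches hand-enumerated cases", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(4, 5, 6))$statistic, 1)
  expect_equal(ks_two_sample(c(1, 3), c(2, 4))$statistic, 0.5)
  expect_error(ks_two_sample(numeric(0), 1:3),
               class = "riscshift_validation_error")
})

test_that("KS implementation agrees with the reference implementation", {
  set.seed(13)
  for (i in 1:100) {
    n1 <- sample(5:80, 1); n2 <- sample(5:80, 1)
    x <- rnorm(n1); y <- rnorm(n2, mean = runif(1, -1, 1))
    got <- ks_two_sample(x, y)
    ref <- suppressWarnings(stats::ks.test(x, y))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-9)
  }
  # p-values: exact branch against ks.test exact, asymptotic against the
  # Kolmogorov series ks.test uses
  x <- rnorm(20); y <- rnorm(25, 0.5)
  expect_equal(ks_two_sample(x, y)$p_value,
               stats::ks.test(x, y, exact = TRUE)$p.value, tolerance = 1e-9)
  x2 <- rnorm(200); y2 <- rnorm(250, 0.2)
  expect_equal(ks_two_sample(x2, y2)$p_value,
               stats::ks.test(x2, y2, exact = FALSE)$p.value, tolerance = 1e-6)
})

test_that("ECDF comparison detects no shift on identical groups", {
  genes <- sprintf("g%03d", 1:120)
  de <- data.frame(gene_id = genes, base_mean = 100,
                   log2fc = rep(rnorm(40), 3), pvalue = 0.5, padj = 0.5)
  sc <- data.frame(gene_id = genes[1:40], n_sites = 40:1, total_reads = 1L)
  sm <- data.frame(gene_id = genes[1:40], n_seed_matched_sites = 1L,
                   seed_matched = TRUE)
  p <- bin_targets(build_profiles(sc, sm, de, expressed = genes),
                   bins = list(all_targets = c(0, 100)))
  # targets' lfc values identical to a subset of non-targets by construction
  cmp <- compare_ecdfs(p)
  expect_equal(cmp$ks_D[cmp$group_label == "all_targets"], 0)
  expect_equal(cmp$median_shift[cmp$group_label == "all_targets"], 0)
  curves <- attr(cmp, "curves")
  expect_true(all(c("all_targets", "non_target") %in% curves$group))

  p_no_ref <- p[p$bin_label != "non_target", ]
  expect_error(compare_ecdfs(p_no_ref), regexp = "reference")
  expect_warning(compare_ecdfs(p, group_labels = c("all_targets", "ghost_bin")),
                 regexp = "empty")
})

test_that("repression magnitude is monotone in occupancy bin across seeds", {
  cfg <- sim_config(n_genes = 300, n_ago_sites = 150, n_fam_sites = 150,
                    n_target_genes = 80, site_overlap_fraction = 0,
                    repression_beta = 0.5, stabilization_gamma = 0,
                    lfc_noise_sd = 0.2, seed_match_fraction = 1)
  tx <- generate_transcriptome(cfg)
  ok <- logical(8)
  for (s in seq_along(ok)) {
    cfg$genome_seed <- 300 + s
    run <- rnai_recovery_run(tx, cfg)
    cmp <- run$comparisons
    top <- cmp$median_shift[cmp$group_label == "top_5_20"]
    mid <- cmp$median_shift[cmp$group_label == "mid_25_100"]
    ok[s] <- top <= mid && mid <= 0
  }
  expect_true(all(ok))
})
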