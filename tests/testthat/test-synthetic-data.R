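test_that("transcriptome generation is deterministic and seed-sensitive", {
  cfg <- sim_config(n_genes = 50, genome_seed = 7)
  a <- generate_transcriptome(cfg)
  b <- generate_transcriptome(cfg)
  expect_identical(a$models, b$models)
  expect_identical(as.character(a$genome), as.character(b$genome))
  cfg8 <- sim_config(n_genes = 50, genome_seed = 8)
  c <- generate_transcriptome(cfg8)
  expect_false(identical(a$models$start, c$models$start))
})

test_that("gene models are complete, non-overlapping and covered by the genome", {
  m <- fix_tx$models
  expect_equal(length(unique(m$gene_id)), fix_cfg$n_genes)
  per_gene <- split(m, m$gene_id)
  for (g in per_gene[1:10]) {
    expect_setequal(unique(g$feature), c("five_utr", "cds", "intron", "three_utr"))
    expect_true(all(g$start < g$end))
  }
  spans <- t(vapply(per_gene, function(g)
    c(min(g$start), max(g$end)), numeric(2)))
  chroms <- vapply(per_gene, function(g) g$chrom[1], character(1))
  for (cn in unique(chroms)) {
    s <- spans[chroms == cn, , drop = FALSE]
    s <- s[order(s[, 1]), , drop = FALSE]
    if (nrow(s) > 1)
      expect_true(all(s[-1, 1] >= s[-nrow(s), 2] + fix_cfg$intergenic_gap_min))
    expect_true(max(s[, 2]) <= Biostrings::nchar(fix_tx$genome[[cn]]))
  }
})

test_that("invalid configuration names the offending field", {
  expect_error(sim_config(n_genes = 1), "n_genes")
  expect_error(sim_config(conversion_rate = 1.2), "conversion_rate")
  expect_error(sim_config(mirna_zipf_exponent = 1), "mirna_zipf_exponent")
  expect_error(sim_config(n_ago_sites = 100, n_fam_sites = 10,
                          site_overlap_fraction = 0.5),
               "site_overlap_fraction")
  expect_error(sim_config(tmt_noise_sd = 0), "tmt_noise_sd")
})

test_that("planted site overlap is exact at the boundaries and in between", {
  base <- function(rho) sim_config(n_genes = 80, genome_seed = 5,
                                   n_ago_sites = 40, n_fam_sites = 40,
                                   n_target_genes = 25,
                                   site_overlap_fraction = rho)
  tx <- generate_transcriptome(base(0))
  t0 <- plant_binding_sites(tx$models, tx$genome, base(0))
  expect_equal(sum(t0$ago_sites$overlapped), 0L)
  t1 <- plant_binding_sites(tx$models, tx$genome, base(1))
  expect_equal(sum(t1$ago_sites$overlapped), 40L)
  t65 <- plant_binding_sites(tx$models, tx$genome, base(0.65))
  expect_equal(sum(t65$ago_sites$overlapped), round(0.65 * 40))

  # independent O(n^2) interval-intersection oracle
  count_overlapped <- function(a, b) {
    sum(vapply(seq_len(nrow(a)), function(i) {
      any(b$chrom == a$chrom[i] & b$strand == a$strand[i] &
            b$start < a$end[i] & b$end > a$start[i])
    }, logical(1)))
  }
  expect_equal(count_overlapped(t65$ago_sites, t65$fam_sites), round(0.65 * 40))
  expect_equal(count_overlapped(t0$ago_sites, t0$fam_sites), 0L)
})

test_that("planted sites sit inside genes with a sense-strand crosslink base", {
  m <- fix_tx$models
  spans <- do.call(rbind, lapply(split(m, m$gene_id), function(g)
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1], strand = g$strand[1],
               start = min(g$start), end = max(g$end))))
  for (tab in list(fix_truth$ago_sites, fix_truth$fam_sites)) {
    i <- match(tab$gene_id, spans$gene_id)
    expect_true(all(tab$chrom == spans$chrom[i]))
    expect_true(all(tab$strand == spans$strand[i]))
    chrseq <- vapply(names(fix_truth$genome), function(nm)
      as.character(fix_truth$genome[[nm]]), character(1))
    base <- substring(chrseq[tab$chrom], tab$crosslink_pos + 1,
                      tab$crosslink_pos + 1)
    expect_true(all(base == ifelse(tab$strand == "+", "T", "A")))
    expect_true(all(tab$crosslink_pos >= tab$start &
                      tab$crosslink_pos < tab$end))
  }
  # AGO sites lie fully inside their gene span (FAM pairs may poke past by
  # at most half a footprint)
  i <- match(fix_truth$ago_sites$gene_id, spans$gene_id)
  expect_true(all(fix_truth$ago_sites$start >= spans$start[i] &
                    fix_truth$ago_sites$end <= spans$end[i]))
})

test_that("gene label sets partition the transcriptome", {
  sets <- list(fix_truth$cobound_genes, fix_truth$ago_only_genes,
               fix_truth$nontarget_genes)
  expect_equal(sum(lengths(sets)), fix_cfg$n_genes)
  expect_equal(length(unique(unlist(sets))), fix_cfg$n_genes)
  bound <- unique(fix_truth$ago_sites$gene_id)
  expect_setequal(c(fix_truth$cobound_genes, fix_truth$ago_only_genes), bound)
  expect_setequal(unique(fix_truth$ago_sites$gene_id[fix_truth$ago_sites$overlapped]),
                  fix_truth$cobound_genes)
})

test_that("conversion marking honours the conversion and error rates", {
  cfg0 <- fix_cfg; cfg0$conversion_rate <- 0; cfg0$error_rate <- 0
  r0 <- simulate_parclip_reads(fix_truth, cfg0, "ago")
  expect_true(all(r0$conversions == ""))

  cfg1 <- fix_cfg; cfg1$conversion_rate <- 1; cfg1$error_rate <- 0
  cfg1$background_read_fraction <- 0
  r1 <- simulate_parclip_reads(fix_truth, cfg1, "ago")
  cx <- fix_truth$ago_sites$crosslink_pos
  conv <- strsplit(r1$conversions, ",", fixed = TRUE)
  covers <- vapply(seq_len(nrow(r1)), function(i)
    any(cx >= r1$start[i] & cx < r1$end[i]), logical(1))
  has_cx_conv <- vapply(conv, function(p)
    length(p) > 0 && any(as.integer(p) %in% cx), logical(1))
  expect_true(all(has_cx_conv[covers]))
  # with error_rate 0, every conversion is a planted crosslink position
  expect_true(all(unlist(lapply(conv, as.integer)) %in% cx))
})

test_that("per-site read counts follow the configured coverage law", {
  cfg <- sim_config(n_genes = 600, genome_seed = 3, n_ago_sites = 500,
                    n_fam_sites = 500, n_target_genes = 300,
                    reads_per_site_mean = 20,
                    reads_per_site_dispersion = 1e6,
                    background_read_fraction = 0)
  tx <- generate_transcriptome(cfg)
  truth <- plant_binding_sites(tx$models, tx$genome, cfg)
  reads <- simulate_parclip_reads(truth, cfg, "ago")
  # sites are >= site_margin apart, so read-to-site attribution by overlap is
  # unambiguous
  site_gr <- GenomicRanges::GRanges(truth$ago_sites$chrom,
    IRanges::IRanges(truth$ago_sites$start + 1, truth$ago_sites$end),
    truth$ago_sites$strand)
  read_gr <- GenomicRanges::GRanges(reads$chrom,
    IRanges::IRanges(reads$start + 1, reads$end), reads$strand)
  cov <- GenomicRanges::countOverlaps(site_gr, read_gr)
  expect_lt(abs(mean(cov) - 20), 2)
})

test_that("planted log2FC follows the repression/stabilization formula", {
  expect_identical(fix_de$true_log2fc,
                   unname(true_lfc_from_truth(fix_truth, fix_cfg)[fix_de$gene_id]))
  # beta = 0: no repression anywhere
  cfg0 <- fix_cfg; cfg0$repression_beta <- 0
  de0 <- simulate_expression_changes(fix_truth, cfg0)
  expect_true(all(de0$true_log2fc == 0))
  # gamma = 1: co-bound genes fully protected
  cfg1 <- fix_cfg; cfg1$stabilization_gamma <- 1
  de1 <- simulate_expression_changes(fix_truth, cfg1)
  expect_true(all(de1$true_log2fc[de1$gene_id %in% fix_truth$cobound_genes] == 0))
  # gamma = 0: the max-occupancy seed-matched gene hits -beta exactly
  cfgm <- fix_cfg; cfgm$stabilization_gamma <- 0
  dem <- simulate_expression_changes(fix_truth, cfgm)
  counts <- table(fix_truth$ago_sites$gene_id)
  seeded <- unique(fix_truth$ago_sites$gene_id[!is.na(fix_truth$ago_sites$seed_motif)])
  top <- names(counts)[counts == max(counts)]
  top_seeded <- intersect(top, seeded)
  expect_true(length(top_seeded) > 0)
  expect_equal(dem$true_log2fc[dem$gene_id %in% top_seeded],
               rep(-fix_cfg$repression_beta, length(top_seeded)))
  # non-targets always at zero
  expect_true(all(fix_de$true_log2fc[fix_de$gene_id %in%
                                       fix_truth$nontarget_genes] == 0))
})

test_that("synthetic DE table has consistent p-values and base means", {
  expect_true(all(fix_de$pvalue >= 0 & fix_de$pvalue <= 1))
  expect_true(all(fix_de$padj >= fix_de$pvalue - 1e-12))
  expect_true(all(fix_de$base_mean > 0))
  # smaller p for larger |observed lfc| by construction
  o <- order(abs(fix_de$log2fc))
  expect_true(all(diff(fix_de$pvalue[o]) <= 1e-12))
})

test_that("miRNA profile has the advertised shape and abundance law", {
  mir <- simulate_mirna_profile(fix_cfg)
  expect_equal(nrow(mir), fix_cfg$n_mirnas)
  expect_true(all(nchar(mir$sequence) %in% c(21, 22)))
  expect_true(all(grepl("^[ACGU]+$", mir$sequence)))
  expect_true(all(diff(mir$count) <= 0))
  expect_identical(mir, simulate_mirna_profile(fix_cfg))
  # the top 200 of 500 concentrate most, but < 95%, of expression
  frac <- sum(mir$count[1:200]) / sum(mir$count)
  expect_gt(frac, 0.5)
  expect_lt(frac, 0.95)
})

test_that("TMT simulation plants a recoverable enriched set", {
  sens <- fpr <- numeric(50)
  for (s in seq_len(50)) {
    cfg <- sim_config(genome_seed = 1000 + s, tmt_n_proteins = 60,
                      tmt_n_enriched = 10, tmt_shift = 1.0, tmt_noise_sd = 0.1)
    tmt <- simulate_tmt_table(cfg)
    res <- test_enriched_interactors(median_center_ratios(tmt$quant))
    hit <- res$protein_id[res$significant]
    sens[s] <- mean(tmt$enriched_proteins %in% hit)
    fpr[s] <- mean(setdiff(res$protein_id, tmt$enriched_proteins) %in% hit)
  }
  expect_gte(mean(sens), 0.95)
  # one-sided filter: background pass rate stays near its nominal level
  expect_lte(mean(fpr), 0.075 / 2 + 0.03)
})
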