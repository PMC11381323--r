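test_that("RPM normalization sums to one million", {
  r <- compute_rpm(data.frame(mirna_id = c("a", "b"), count = c(3, 1)))
  expect_equal(r$rpm, c(750000, 250000))
  one <- compute_rpm(data.frame(mirna_id = "a", count = 5))
  expect_equal(one$rpm, 1e6)
  expect_error(compute_rpm(data.frame(mirna_id = c("a", "b"), count = c(0, 0))),
               class = "riscshift_validation_error")
  set.seed(1)
  many <- compute_rpm(data.frame(mirna_id = sprintf("m%03d", 1:300),
                                 count = sample(1:1000, 300, replace = TRUE)))
  expect_equal(sum(many$rpm), 1e6, tolerance = 1e-6)
})

test_that("6mer seed extraction takes positions 2-7 and reverse-complements", {
  let7 <- extract_seed6("UGAGGUAGUAGGUUGUAUAGUU")
  expect_equal(let7$seed6_rna, "GAGGUA")
  expect_equal(let7$target_motif_dna, "TACCTC")
  aaa <- extract_seed6("AAAAAAAA")
  expect_equal(aaa$seed6_rna, "AAAAAA")
  expect_equal(aaa$target_motif_dna, "TTTTTT")
  expect_error(extract_seed6("ACGUAC"), class = "riscshift_validation_error")
  # round trip: motif is the exact reverse complement of the seed
  set.seed(2)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "U"), 21, replace = TRUE), collapse = "")
    e <- extract_seed6(s)
    expect_equal(revcomp_chr(chartr("U", "T", e$seed6_rna)),
                 e$target_motif_dna)
  }
})

test_that("top-miRNA selection reports cumulative fraction and breaks ties", {
  mir <- compute_rpm(simulate_mirna_profile(fix_cfg))
  ss <- select_top_mirnas(mir, 200L)
  expect_equal(nrow(ss$entries), 200L)
  expect_equal(ss$cumulative_fraction, sum(ss$entries$rpm) / 1e6)
  expect_lt(ss$cumulative_fraction, 0.95)

  top1 <- select_top_mirnas(mir, 1L)
  expect_equal(top1$entries$mirna_id, mir$mirna_id[which.max(mir$rpm)])

  tied <- data.frame(mirna_id = c("mir-z", "mir-a", "mir-m"),
                     sequence = rep("UGAGGUAGUAGGUUGUAUAGUU", 3),
                     count = c(10, 5, 5))
  sel <- select_top_mirnas(compute_rpm(tied), 2L)
  expect_setequal(sel$entries$mirna_id, c("mir-z", "mir-a"))

  expect_message(all3 <- suppressWarnings(select_top_mirnas(compute_rpm(tied), 5L)),
                 "only 3")
  expect_equal(nrow(all3$entries), 3L)

  conc <- data.frame(mirna_id = c("a", "b", "c"),
                     sequence = rep("UGAGGUAGUAGGUUGUAUAGUU", 3),
                     count = c(1000, 1000, 1))
  expect_warning(select_top_mirnas(compute_rpm(conc), 2L), "95")
})

test_that("seed scanning counts overlapping exact matches only", {
  ss <- seed_set_from_motifs("TACCTC")
  expect_equal(scan_seed_matches("GGTACCTCGG", ss)$n_matches, 1L)
  expect_equal(scan_seed_matches("TTTTTTT", seed_set_from_motifs("TTTTTT"))$n_matches,
               2L)
  expect_equal(scan_seed_matches("GGTACCTCGG",
                                 seed_set_from_motifs(character(0)))$n_matches,
               0L)
  expect_error(scan_seed_matches("GGTAXCTCGG", ss),
               class = "riscshift_validation_error")
  expect_equal(scan_seed_matches("GGTANCTCGG", ss)$n_matches, 0L)
})

test_that("seed scanning agrees exactly with the sliding-window oracle", {
  set.seed(11)
  seqs <- vapply(sample(20:60, 300, replace = TRUE), function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  motifs <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE), collapse = ""),
    character(1))
  got <- scan_seed_matches(seqs, seed_set_from_motifs(motifs))
  want <- vapply(seqs, function(s)
    sum(vapply(motifs, function(m) oracle_motif_count(s, m), integer(1))),
    integer(1), USE.NAMES = FALSE)
  expect_identical(got$n_matches, want)
})

test_that("planted seed motifs are found in strand-aware site sequences", {
  sites <- fix_truth$ago_sites
  seqs <- site_sequences(sites, fix_truth$genome, flank = 10L)
  matches <- scan_seed_matches(seqs, seed_set_from_motifs(fix_truth$seed_motifs))
  planted <- !is.na(sites$seed_motif)
  expect_true(all(matches$n_matches[planted] >= 1L))
  expect_true(any(sites$strand == "-"))  # the check exercises both strands
  per_gene <- aggregate_seed_matches(sites, matches)
  genes_with_motif <- unique(sites$gene_id[planted])
  expect_true(all(genes_with_motif %in%
                    per_gene$gene_id[per_gene$seed_matched]))
})
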