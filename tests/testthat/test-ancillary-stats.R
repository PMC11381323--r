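quant_from_ratios <- function(ratios, block = NULL) {
  df <- data.frame(protein_id = sprintf("p%03d", seq_along(ratios)),
                   ko_1 = ratios, ko_2 = ratios,
                   wt_1 = rep(0, length(ratios)), wt_2 = rep(0, length(ratios)),
                   stringsAsFactors = FALSE)
  if (!is.null(block)) df$block <- block
  df
}

ratios_of <- function(quant) {
  rowMeans(quant[, c("ko_1", "ko_2")]) - rowMeans(quant[, c("wt_1", "wt_2")])
}

test_that("median centering zeroes each block's median ratio and is idempotent", {
  q <- median_center_ratios(quant_from_ratios(c(1, 2, 3)))
  expect_equal(ratios_of(q), c(-1, 0, 1))
  expect_equal(median_center_ratios(q), q)

  set.seed(4)
  q2 <- median_center_ratios(quant_from_ratios(rnorm(500, 3, 2)))
  expect_lt(abs(median(ratios_of(q2))), 1e-12)

  qb <- median_center_ratios(quant_from_ratios(c(1, 2, 3, 10, 20, 30),
                                               block = rep(c("x", "y"), each = 3)))
  expect_equal(median(ratios_of(qb)[1:3]), 0)
  expect_equal(median(ratios_of(qb)[4:6]), 0)

  expect_error(median_center_ratios(quant_from_ratios(numeric(0))),
               class = "riscshift_validation_error")
})

test_that("per-protein t-test matches the textbook pooled formula", {
  set.seed(5)
  n <- 50
  q <- data.frame(protein_id = sprintf("p%03d", 1:n),
                  ko_1 = rnorm(n), ko_2 = rnorm(n), ko_3 = rnorm(n),
                  wt_1 = rnorm(n), wt_2 = rnorm(n), wt_3 = rnorm(n))
  res <- test_enriched_interactors(q)
  for (i in seq_len(n)) {
    ko <- as.numeric(q[i, c("ko_1", "ko_2", "ko_3")])
    wt <- as.numeric(q[i, c("wt_1", "wt_2", "wt_3")])
    sp2 <- (2 * var(ko) + 2 * var(wt)) / 4
    tstat <- (mean(ko) - mean(wt)) / sqrt(sp2 * (1 / 3 + 1 / 3))
    p <- 2 * pt(-abs(tstat), df = 4)
    expect_equal(res$p_value[i], p, tolerance = 1e-9)
  }
})

test_that("enrichment thresholds are inclusive on FC, strict on p", {
  q <- data.frame(protein_id = c("hit", "weak_fc"),
                  ko_1 = c(20.60, 20.30), ko_2 = c(20.70, 20.40),
                  ko_3 = c(20.65, 20.35),
                  wt_1 = c(20.02, 20.02), wt_2 = c(20.08, 20.08),
                  wt_3 = c(20.05, 20.05))
  res <- test_enriched_interactors(q)
  # fold-change gate: log2 ratio must reach log2(1.5) = 0.585
  expect_true(res$mean_log2_ratio[1] >= log2(1.5))
  expect_true(res$significant[1])
  expect_lt(res$mean_log2_ratio[2], log2(1.5))
  expect_false(res$significant[2])
  # p gate is strict: at p_threshold equal to the computed p, not significant
  p_hit <- res$p_value[1]
  at <- test_enriched_interactors(q, p_threshold = p_hit)
  expect_false(at$significant[1])
  above <- test_enriched_interactors(q, p_threshold = p_hit + 1e-12)
  expect_true(above$significant[1])
})

test_that("zero-variance proteins are flagged, never significant", {
  q <- data.frame(protein_id = "flat",
                  ko_1 = 21, ko_2 = 21, ko_3 = 21,
                  wt_1 = 20, wt_2 = 20, wt_3 = 20)
  res <- test_enriched_interactors(q)
  expect_true(res$degenerate)
  expect_false(res$significant)
  expect_true(is.na(res$p_value))
})

test_that("DE filter applies strict printed thresholds and overlaps", {
  de <- data.frame(
    gene_id = c("up_ok", "padj_at", "down_ok", "lfc_at", "na_row"),
    base_mean = 100,
    log2fc = c(0.6, 0.6, -0.6, 0.5, NA),
    pvalue = 0.001,
    padj = c(0.005, 0.01, 0.001, 0.005, 0.001))
  f <- de_filter(de)
  expect_equal(f$up, "up_ok")
  expect_equal(f$down, "down_ok")
  expect_equal(f$n_up + f$n_down, 2L)
  ov <- overlap_significant(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(ov$n_overlap, 2L)
  expect_equal(ov$overlap, c("b", "c"))
})

test_that("miRNA differential handles pseudocounts and fixed library size", {
  same <- data.frame(mirna_id = c("a", "b"), count = c(100, 300))
  expect_true(all(mirna_differential(same, same)$log2fc == 0))

  wt <- data.frame(mirna_id = c("a", "b"), count = c(100, 100))
  ko <- data.frame(mirna_id = c("a", "b"), count = c(200, 0))
  d <- mirna_differential(wt, ko)
  expect_equal(d$log2fc[d$mirna_id == "a"], log2((201 / 200) / (101 / 200)),
               tolerance = 1e-12)
  expect_true(is.finite(d$log2fc[d$mirna_id == "b"]))
  expect_error(mirna_differential(wt, data.frame(mirna_id = "a", count = 0)),
               class = "riscshift_validation_error")
})

test_that("Malthusian fit is exact on noiseless data and robust under noise", {
  t <- 0:6
  f <- fit_malthusian_growth(t, 1000 * 2^t)
  expect_equal(f$rate, log(2), tolerance = 1e-9)
  expect_equal(f$doubling_time, 1.0, tolerance = 1e-9)
  expect_equal(f$n0, 1000, tolerance = 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  f2 <- fit_malthusian_growth(t, 500 * exp(0.3 * t))
  expect_equal(f2$rate, 0.3, tolerance = 1e-9)
  expect_equal(f2$doubling_time, log(2) / 0.3, tolerance = 1e-9)

  dec <- fit_malthusian_growth(t, 1000 * exp(-0.2 * t))
  expect_false(dec$k_positive)
  expect_true(is.na(dec$doubling_time))

  expect_error(fit_malthusian_growth(0:1, c(1, 2)),
               class = "riscshift_validation_error")
  expect_error(fit_malthusian_growth(t, c(1000, -5, rep(10, 5))),
               class = "riscshift_validation_error")

  set.seed(6)
  rel_err <- replicate(100, {
    y <- 1000 * 2^t * exp(rnorm(length(t), 0, 0.05))
    abs(fit_malthusian_growth(t, y)$doubling_time - 1)
  })
  expect_true(all(rel_err < 0.10))
})

test_that("simulated growth counts recover the configured doubling time", {
  g <- simulate_growth_counts(fix_cfg)
  fit <- fit_malthusian_growth(g$day, g$count)
  expect_equal(fit$doubling_time, log(2) / fix_cfg$growth_rate,
               tolerance = 0.1)
  expect_gt(fit$r_squared, 0.95)
})
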