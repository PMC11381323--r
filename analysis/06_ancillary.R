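#!/usr/bin/env Rscript
# Stage 6 — ancillary statistics.
#
# The remaining defined computations: the TMT interactome enrichment filter
# (median-centred log2 ratios, Student's t-test, 1.5-fold & P < 0.075), the
# DE threshold filter (padj < 0.01, |log2FC| > 0.5), a miRNA differential
# profile, and the Malthusian growth fit with its doubling time.

suppressMessages(library(riscshift))

inp <- "results/study/inputs"
out <- "results/study"

tmt <- read.delim(file.path(inp, "tmt.tsv"))
enr <- test_enriched_interactors(median_center_ratios(tmt))
write.table(enr, file.path(out, "tmt_enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("TMT: %d of %d proteins pass the 1.5-fold & P<0.075 filter",
                sum(enr$significant), nrow(enr)))

de <- read_de_table(file.path(inp, "de.tsv"))
f <- de_filter(de)
message(sprintf("DE filter: %d up, %d down at padj<0.01 & |log2FC|>0.5",
                f$n_up, f$n_down))

mirnas <- read_mirna_profile(file.path(inp, "mirna.fa"),
                             file.path(inp, "mirna_counts.tsv"))
ko <- riscshift:::perturb_mirna_counts(mirnas, sim_config(genome_seed = 1L))
md <- mirna_differential(mirnas[, c("mirna_id", "count")], ko)
write.table(md, file.path(out, "mirna_differential.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("miRNA differential: %d species with |log2FC| > 0.5",
                sum(abs(md$log2fc) > 0.5)))

growth <- read_table(file.path(inp, "growth.tsv"), schema_growth(), "growth")
fit <- fit_malthusian_growth(growth$day, growth$count)
message(sprintf("growth: doubling time %.2f days (r^2 = %.3f)",
                fit$doubling_time, fit$r_squared))
jsonlite::write_json(
  list(n_enriched = sum(enr$significant), de_up = f$n_up, de_down = f$n_down,
       doubling_days = fit$doubling_time, r_squared = fit$r_squared),
  file.path(out, "ancillary_summary.json"), auto_unbox = TRUE, digits = 6)
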