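#!/usr/bin/env Rscript
# Stage 3 — feature annotation and the miRNA seed filter.
#
# Assigns each called cluster to a gene and transcript feature category by
# its conversion mode location, summarizes where AGO reads land (the planted
# study puts 70% of AGO sites in 3'UTRs, so the 3'UTR should dominate), then
# builds the expressed-miRNA seed set (top 200 by RPM) and scans every AGO
# cluster +/- 10 nt for 6mer seed matches.

suppressMessages(library(riscshift))

inp <- "results/study/inputs"
out <- "results/study"

genome <- read_genome_fasta(file.path(inp, "genome.fa"))
models <- read_annotation(file.path(inp, "annotation.tsv"))
reads_ago <- read_alignments(file.path(inp, "reads_ago.tsv"))

for (side in c("ago", "fam")) {
  cl <- read_clusters_bed(file.path(out, sprintf("clusters_%s.bed", side)))
  ann <- assign_clusters(cl, models)
  write_clusters_bed(ann, file.path(out, sprintf("clusters_%s_annotated.bed", side)))
}
ann_ago <- read_clusters_bed(file.path(out, "clusters_ago_annotated.bed"))

dist <- summarize_read_distribution(reads_ago, ann_ago)
write.table(dist, file.path(out, "read_distribution_ago.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("AGO read distribution: %s",
                paste(sprintf("%s %.1f%%", dist$category, 100 * dist$fraction),
                      collapse = ", ")))

mirnas <- read_mirna_profile(file.path(inp, "mirna.fa"),
                             file.path(inp, "mirna_counts.tsv"))
seed_set <- select_top_mirnas(compute_rpm(mirnas), 200L)
message(sprintf("top %d miRNAs account for %.1f%% of miRNA expression",
                seed_set$top_n, 100 * seed_set$cumulative_fraction))
write.table(seed_set$entries, file.path(out, "seed_set.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

matches <- scan_seed_matches(site_sequences(ann_ago, genome, flank = 10L),
                             seed_set)
seed_tab <- cbind(ann_ago[, c("cluster_id", "gene_id")], matches)
write.table(seed_tab, file.path(out, "seed_matches.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
per_gene <- aggregate_seed_matches(ann_ago, matches)
message(sprintf("%d of %d bound genes carry a 6mer seed match",
                sum(per_gene$seed_matched), nrow(per_gene)))
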