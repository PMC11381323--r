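#!/usr/bin/env Rscript
# Stage 2 — call binding-site clusters.
#
# Reads the simulated alignments back from disk (the TSV dialect; the SAM
# route is equivalent and exercised by the test suite), calls conversion
# clusters for AGO and FAM120A with the default caller parameters, and
# benchmarks the calls against the planted truth. Expect precision and recall
# well above 0.9 at the reference conversion rate of 0.3.

suppressMessages(library(riscshift))

inp <- "results/study/inputs"
out <- "results/study"

genome <- read_genome_fasta(file.path(inp, "genome.fa"))
truth <- read_truth_json(file.path(inp, "truth.json"))

for (side in c("ago", "fam")) {
  reads <- read_alignments(file.path(inp, sprintf("reads_%s.tsv", side)))
  clusters <- call_clusters(reads, genome)
  write_clusters_bed(clusters, file.path(out, sprintf("clusters_%s.bed", side)))
  sites <- if (side == "ago") truth$ago_sites else truth$fam_sites
  bm <- benchmark_cluster_calls(clusters, sites)
  message(sprintf(
    "%s: %d reads -> %d clusters | precision %.3f, recall %.3f vs %d planted sites",
    toupper(side), nrow(reads), nrow(clusters), bm$precision, bm$recall,
    bm$n_sites))
}
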