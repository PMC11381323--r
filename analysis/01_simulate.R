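#!/usr/bin/env Rscript
# Stage 1 — simulate the study.
#
# Generates the full synthetic study at the reference conditions: a 1000-gene
# toy transcriptome, 400 AGO and 400 FAM120A binding sites with a planted 65%
# site overlap, PAR-CLIP reads for both proteins, the miRNA profile, the DE
# table with planted occupancy-scaled repression (attenuated on co-bound
# genes), the TMT interactome table and a growth curve. Everything downstream
# stages consume is written under results/study/inputs; the planted truth
# goes to truth.json for later benchmarking.

suppressMessages(library(riscshift))

out <- "results/study/inputs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(genome_seed = 1L)

tx <- generate_transcriptome(cfg)
mirnas <- simulate_mirna_profile(cfg)
truth <- plant_binding_sites(tx$models, tx$genome, cfg)
reads_ago <- simulate_parclip_reads(truth, cfg, "ago")
reads_fam <- simulate_parclip_reads(truth, cfg, "fam")
de <- simulate_expression_changes(truth, cfg)
tmt <- simulate_tmt_table(cfg)
growth <- simulate_growth_counts(cfg)

write_genome_fasta(truth$genome, file.path(out, "genome.fa"))
write_annotation(tx$models, file.path(out, "annotation.tsv"))
export_gtf(tx$models, file.path(out, "annotation.gtf"))
write_reads_tsv(reads_ago, file.path(out, "reads_ago.tsv"))
write_reads_sam(reads_ago, truth$genome, file.path(out, "reads_ago.sam"))
write_reads_tsv(reads_fam, file.path(out, "reads_fam.tsv"))
write_mirna_profile(mirnas, file.path(out, "mirna.fa"),
                    file.path(out, "mirna_counts.tsv"))
write_de_table(de, file.path(out, "de.tsv"))
write.table(tmt$quant, file.path(out, "tmt.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(growth, file.path(out, "growth.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write_truth_json(truth, file.path(out, "truth.json"))

message(sprintf(
  "simulated %d genes on %d chromosomes; %d AGO + %d FAM sites (overlap %.2f, %d co-bound genes); %d + %d reads",
  cfg$n_genes, length(truth$genome), nrow(truth$ago_sites),
  nrow(truth$fam_sites), mean(truth$ago_sites$overlapped),
  length(truth$cobound_genes), nrow(reads_ago), nrow(reads_fam)))
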