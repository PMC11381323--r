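# Shared small-scale fixtures, generated once per test run.

fix_cfg <- sim_config(n_genes = 120, genome_seed = 42, n_ago_sites = 60,
                      n_fam_sites = 60, n_target_genes = 40)
fix_tx <- generate_transcriptome(fix_cfg)
fix_truth <- plant_binding_sites(fix_tx$models, fix_tx$genome, fix_cfg)
fix_reads <- simulate_parclip_reads(fix_truth, fix_cfg, "ago")
fix_de <- simulate_expression_changes(fix_truth, fix_cfg)

# Tiny single-chromosome genome with a controllable sequence.
make_genome <- function(seqs) {
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- names(seqs)
  g
}

make_reads <- function(chrom, start, end, strand = "+", conversions = "",
                       ids = NULL) {
  n <- max(length(chrom), length(start), length(end), length(strand),
           length(conversions))
  data.frame(
    read_id = if (is.null(ids)) sprintf("r%03d", seq_len(n)) else ids,
    chrom = rep_len(chrom, n), start = rep_len(start, n),
    end = rep_len(end, n), strand = rep_len(strand, n),
    conversions = rep_len(conversions, n), n_other_mismatches = 0L,
    stringsAsFactors = FALSE)
}

# Brute-force union-find over pairwise read overlap (gap <= merge_gap):
# the O(n^2) oracle for read grouping.
oracle_groups <- function(reads, merge_gap = 0L) {
  n <- nrow(reads)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    if (reads$chrom[i] == reads$chrom[j] &&
        reads$strand[i] == reads$strand[j] &&
        reads$start[i] <= reads$end[j] + merge_gap &&
        reads$start[j] <= reads$end[i] + merge_gap) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Naive sliding-window motif counter: the seed-scanning oracle.
oracle_motif_count <- function(seq, motif) {
  n <- nchar(seq); m <- nchar(motif)
  if (n < m) return(0L)
  hits <- 0L
  for (i in seq_len(n - m + 1L)) {
    if (substr(seq, i, i + m - 1L) == motif) hits <- hits + 1L
  }
  hits
}

# Seed set wrapper around raw DNA motifs (for scanning planted sites).
seed_set_from_motifs <- function(motifs, ids = NULL) {
  structure(list(
    entries = data.frame(
      mirna_id = if (is.null(ids)) sprintf("m%02d", seq_along(motifs)) else ids,
      seed6_rna = dna_to_rna_chr(revcomp_chr(motifs)),
      target_motif_dna = motifs, rpm = rep(NA_real_, length(motifs)),
      stringsAsFactors = FALSE),
    top_n = length(motifs), cumulative_fraction = NA_real_
  ), class = "seed_set")
}

revcomp_chr <- function(x) {
  vapply(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE),
         function(b) paste(rev(b), collapse = ""), character(1),
         USE.NAMES = FALSE)
}
dna_to_rna_chr <- function(x) chartr("T", "U", x)
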