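FEATURE_CLASSES <- c("five_utr", "cds", "intron", "three_utr")

# Transcript-order slots of every simulated gene model: a single isoform with
# one intron splitting the CDS. Feature labels per slot, 5' -> 3'.
TX_SLOT_FEATURE <- c("five_utr", "cds", "intron", "cds", "three_utr")

#' Generate a toy transcriptome
#'
#' Lays out `n_genes` non-overlapping single-isoform gene models on as many
#' chromosomes as needed (`genes_per_chrom` genes each), draws a random genome
#' sequence covering them, and returns both. Every gene carries a 5'UTR, a CDS
#' split by one intron, and a 3'UTR; strands are assigned at random and all
#' coordinates are 0-based half-open (BED convention).
#'
#' @param config A [sim_config()] object.
#' @return A list of class `"transcriptome"` with elements `genome` (a named
#'   [Biostrings::DNAStringSet]) and `models` (a data.frame with columns
#'   `gene_id`, `transcript_id`, `chrom`, `strand`, `feature`, `start`, `end`,
#'   `rank`, where `rank` is the feature's 5'-to-3' order in the transcript).
#' @export
generate_transcriptome <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$genome_seed, 1L))
  n <- config$n_genes

  # Feature lengths in transcript order: 5'UTR, CDS exon 1, intron, CDS exon 2,
  # 3'UTR. The 3'UTR is drawn longest to leave room for binding sites.
  len <- cbind(
    sample(80:200, n, replace = TRUE),
    sample(150:400, n, replace = TRUE),
    sample(100:300, n, replace = TRUE),
    sample(150:400, n, replace = TRUE),
    sample(250:600, n, replace = TRUE)
  )
  gene_len <- rowSums(len)
  gap <- config$intergenic_gap_min + sample(0:200, n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  chrom_idx <- (seq_len(n) - 1L) %/% config$genes_per_chrom + 1L
  chrom <- sprintf("chr%d", chrom_idx)

  step <- gene_len + gap
  gene_start <- 200L + as.integer(ave(step, chrom_idx,
                                      FUN = function(v) cumsum(v) - v))

  idx_gene <- rep(seq_len(n), each = 5L)
  slot <- rep(1:5, times = n)                      # genomic order within gene
  tx_idx <- ifelse(strand[idx_gene] == "+", slot, 6L - slot)
  feat_len <- len[cbind(idx_gene, tx_idx)]
  offset <- as.integer(ave(feat_len, idx_gene, FUN = function(v) cumsum(v) - v))
  start <- gene_start[idx_gene] + offset
  gene_id <- sprintf("g%04d", seq_len(n))

  models <- data.frame(
    gene_id = gene_id[idx_gene],
    transcript_id = paste0(gene_id[idx_gene], ".t1"),
    chrom = chrom[idx_gene],
    strand = strand[idx_gene],
    feature = TX_SLOT_FEATURE[tx_idx],
    start = start,
    end = start + feat_len,
    rank = tx_idx,
    stringsAsFactors = FALSE
  )

  chrom_names <- sprintf("chr%d", seq_len(max(chrom_idx)))
  chrom_len <- vapply(seq_along(chrom_names), function(ci) {
    max(models$end[models$chrom == chrom_names[ci]]) + 200L
  }, integer(1))
  genome <- Biostrings::DNAStringSet(vapply(chrom_len, function(L) {
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
  }, character(1)))
  names(genome) <- chrom_names

  structure(list(genome = genome, models = models), class = "transcriptome")
}
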