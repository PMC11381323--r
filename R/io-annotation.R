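#' Write / read the genome FASTA
#'
#' @param genome A named `DNAStringSet`.
#' @param path FASTA path.
#' @return The path (write) or a `DNAStringSet` with clean names (read).
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

ANNOTATION_COLUMNS <- c("gene_id", "transcript_id", "chrom", "strand",
                        "feature", "start", "end", "rank")

#' Write / read transcript annotation ("GTF-lite" TSV)
#'
#' The annotation dialect is an 8-column TSV: `gene_id`, `transcript_id`,
#' `chrom`, `strand`, `feature` (one of `five_utr`, `cds`, `intron`,
#' `three_utr`), `start`, `end` (0-based half-open) and `rank` (5'-to-3'
#' feature order within the transcript). [export_gtf()] converts the same
#' models to standard 1-based GTF.
#'
#' @param models Transcript-model data.frame.
#' @param path File path.
#' @return The path (write) or the validated models data.frame (read).
#' @export
write_annotation <- function(models, path) {
  rs_write_tsv(models[, ANNOTATION_COLUMNS], path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  df <- read_table(path, c(gene_id = "character", transcript_id = "character",
                           chrom = "character", strand = "character",
                           feature = "character", start = "integer",
                           end = "integer", rank = "integer"),
                   "annotation")
  if (!all(df$feature %in% FEATURE_CLASSES))
    rs_schema_error("annotation", sprintf(
      "unknown feature class '%s'",
      setdiff(df$feature, FEATURE_CLASSES)[1]))
  validate_interval(df$chrom, df$start, df$end, df$strand, "annotation")
  # within-transcript invariants: shared chrom/strand, non-overlapping rows
  for (tx in split(df, df$transcript_id)) {
    if (length(unique(tx$chrom)) != 1L || length(unique(tx$strand)) != 1L)
      rs_schema_error("annotation", sprintf(
        "transcript '%s' mixes chromosomes or strands", tx$transcript_id[1]))
    tx <- tx[order(tx$start), ]
    if (nrow(tx) > 1L && any(tx$start[-1] < tx$end[-nrow(tx)]))
      rs_schema_error("annotation", sprintf(
        "transcript '%s' has overlapping feature intervals", tx$transcript_id[1]))
  }
  df[order(df$chrom, df$start), ]
}

#' Export transcript models as standard GTF
#'
#' Maps the package's feature classes to conventional GTF types
#' (`five_prime_utr`, `CDS`, `intron`, `three_prime_utr`) and writes 1-based
#' GTF via rtracklayer.
#'
#' @param models Transcript-model data.frame.
#' @param path GTF output path.
#' @return The path, invisibly.
#' @export
export_gtf <- function(models, path) {
  type_map <- c(five_utr = "five_prime_utr", cds = "CDS", intron = "intron",
                three_utr = "three_prime_utr")
  gr <- as_granges0(models$chrom, models$start, models$end, models$strand)
  S4Vectors::mcols(gr)$type <- unname(type_map[models$feature])
  S4Vectors::mcols(gr)$gene_id <- models$gene_id
  S4Vectors::mcols(gr)$transcript_id <- models$transcript_id
  S4Vectors::mcols(gr)$exon_number <- models$rank
  S4Vectors::mcols(gr)$phase <- ifelse(models$feature == "cds", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
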