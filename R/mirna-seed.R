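#' Reads-per-million normalization for miRNA counts
#'
#' @param mirnas Data.frame with `mirna_id` and `count` columns.
#' @return The input with an `rpm` column summing to 1e6.
#' @export
compute_rpm <- function(mirnas) {
  total <- sum(mirnas$count)
  if (!is.finite(total) || total <= 0)
    rs_validation_error("compute_rpm: total miRNA count must be > 0")
  mirnas$rpm <- mirnas$count / total * 1e6
  mirnas
}

#' Extract the 6mer seed and its target motif
#'
#' The canonical 6mer seed is miRNA positions 2-7 (1-based); a target site is
#' its reverse complement in the bound RNA, reported here in DNA alphabet for
#' genome scanning.
#'
#' @param sequence A miRNA sequence (RNA or DNA alphabet), length >= 7.
#' @return A list with `seed6_rna` and `target_motif_dna`.
#' @export
extract_seed6 <- function(sequence) {
  if (is.na(sequence) || nchar(sequence) < 7L)
    rs_validation_error("extract_seed6: sequence must be at least 7 nt")
  seed_rna <- dna_to_rna(toupper(substr(sequence, 2L, 7L)))
  if (!grepl("^[ACGU]{6}$", seed_rna))
    rs_validation_error("extract_seed6: seed contains non-ACGU characters")
  list(seed6_rna = seed_rna,
       target_motif_dna = revcomp_dna(rna_to_dna(seed_rna)))
}

#' Select the top expressed miRNAs and build the seed set
#'
#' Takes the `top_n` records by RPM (ties broken toward the lexicographically
#' smaller `mirna_id`), extracts each 6mer seed and target motif, and records
#' the cumulative expression fraction the selection accounts for. A warning is
#' issued when that fraction reaches 95\%, since the analysis this feeds
#' assumes the top set accounts for less than 95\% of miRNA expression; with
#' fewer records than `top_n`, all are used with a message.
#'
#' @param mirnas RPM-normalized miRNA data.frame (see [compute_rpm()]).
#' @param top_n Number of top miRNAs to keep (default 200).
#' @return A list of class `"seed_set"`: `entries` (data.frame `mirna_id`,
#'   `seed6_rna`, `target_motif_dna`, `rpm`), `top_n`,
#'   `cumulative_fraction`.
#' @export
select_top_mirnas <- function(mirnas, top_n = 200L) {
  if (!"rpm" %in% names(mirnas)) mirnas <- compute_rpm(mirnas)
  if (nrow(mirnas) < top_n) {
    message(sprintf("select_top_mirnas: only %d records available (top_n = %d)",
                    nrow(mirnas), top_n))
    top_n <- nrow(mirnas)
  }
  ord <- order(-mirnas$rpm, mirnas$mirna_id)
  top <- mirnas[ord[seq_len(top_n)], , drop = FALSE]
  cum_frac <- sum(top$rpm) / 1e6
  if (cum_frac >= 0.95)
    warning(sprintf(
      "top %d miRNAs account for %.1f%% of expression (expected < 95%%)",
      top_n, 100 * cum_frac))
  seeds <- lapply(top$sequence, extract_seed6)
  structure(list(
    entries = data.frame(
      mirna_id = top$mirna_id,
      seed6_rna = vapply(seeds, `[[`, character(1), "seed6_rna"),
      target_motif_dna = vapply(seeds, `[[`, character(1), "target_motif_dna"),
      rpm = top$rpm, stringsAsFactors = FALSE),
    top_n = top_n,
    cumulative_fraction = cum_frac
  ), class = "seed_set")
}

#' Extract site sequences from the genome
#'
#' Returns the sense-strand sequence of each site interval extended by
#' `flank` nt on both sides; minus-strand sites are reverse-complemented so
#' the returned string reads 5' to 3' on the bound RNA.
#'
#' @param sites Data.frame with `chrom`, `start`, `end`, `strand` (0-based
#'   half-open).
#' @param genome Named `DNAStringSet`.
#' @param flank Flank width in nt (default 10).
#' @return Character vector of sequences, one per site.
#' @export
site_sequences <- function(sites, genome, flank = 10L) {
  vapply(seq_len(nrow(sites)), function(i) {
    L <- Biostrings::nchar(genome[[sites$chrom[i]]])
    s <- max(0L, sites$start[i] - flank)
    e <- min(L, sites$end[i] + flank)
    seq <- as.character(Biostrings::subseq(genome[[sites$chrom[i]]], s + 1L, e))
    if (sites$strand[i] == "-") revcomp_dna(seq) else seq
  }, character(1))
}

#' Scan site sequences for 6mer seed matches
#'
#' Exact, case-insensitive substring matching of every target motif in the
#' seed set against each site sequence; overlapping occurrences all count and
#' `N` never matches. Sequences must be ACGTN.
#'
#' @param site_seqs Character vector of sense-strand site sequences (see
#'   [site_sequences()]).
#' @param seed_set A [select_top_mirnas()] seed set.
#' @return A data.frame with one row per site: `n_matches` (total motif
#'   occurrences) and `matched_mirnas` (comma-separated ids, `""` if none).
#' @export
scan_seed_matches <- function(site_seqs, seed_set) {
  stopifnot(inherits(seed_set, "seed_set"))
  site_seqs <- toupper(site_seqs)
  if (length(site_seqs) && any(grepl("[^ACGTN]", site_seqs)))
    rs_validation_error("scan_seed_matches: sequences must contain only ACGTN")
  motifs <- seed_set$entries$target_motif_dna
  ids <- seed_set$entries$mirna_id
  n <- length(site_seqs)
  n_matches <- integer(n)
  matched <- character(n)
  if (n == 0L) {
    return(data.frame(n_matches = integer(0), matched_mirnas = character(0),
                      stringsAsFactors = FALSE))
  }
  if (length(motifs)) {
    subj <- Biostrings::DNAStringSet(site_seqs)
    counts <- vapply(motifs, function(m) {
      Biostrings::vcountPattern(m, subj, fixed = TRUE)
    }, integer(n))
    counts <- matrix(counts, nrow = n)
    n_matches <- as.integer(rowSums(counts))
    matched <- vapply(seq_len(n), function(i) {
      paste(unique(ids[counts[i, ] > 0L]), collapse = ",")
    }, character(1))
  }
  data.frame(n_matches = n_matches, matched_mirnas = matched,
             stringsAsFactors = FALSE)
}

#' Per-gene seed-match aggregation
#'
#' @param sites Site or cluster data.frame with a `gene_id` column.
#' @param matches Output of [scan_seed_matches()] aligned to `sites` rows.
#' @return Data.frame `gene_id`, `n_seed_matched_sites`, `seed_matched`.
#' @export
aggregate_seed_matches <- function(sites, matches) {
  stopifnot(nrow(sites) == nrow(matches))
  keep <- !is.na(sites$gene_id)
  tab <- tapply(matches$n_matches[keep] > 0L, sites$gene_id[keep], sum)
  data.frame(gene_id = names(tab),
             n_seed_matched_sites = as.integer(tab),
             seed_matched = as.integer(tab) > 0L,
             stringsAsFactors = FALSE,
             row.names = NULL)
}
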