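# Generic TSV plumbing. All text I/O is UTF-8; gzip is transparent on read
# (R's file() sniffs the magic bytes) and chosen on write by a .gz suffix.

rs_write_tsv <- function(df, path, comment = NULL) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w", encoding = "UTF-8")
         else file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

rs_read_tsv <- function(path) {
  if (!file.exists(path))
    rs_stop(sprintf("file not found: '%s'", path), "riscshift_io_error")
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE,
             comment.char = "#", encoding = "UTF-8")
}

#' Read a schema-checked TSV table
#'
#' Reads a tab-separated table and validates it against a named schema: every
#' schema column must be present and coercible to the declared type
#' (`"character"`, `"numeric"` or `"integer"`). Extra columns are kept.
#'
#' @param path File path (plain or gzip TSV).
#' @param schema Named character vector mapping required column names to types.
#' @param what Label used in error messages.
#' @return The validated data.frame.
#' @export
read_table <- function(path, schema, what = "table") {
  df <- rs_read_tsv(path)
  for (col in names(schema)) {
    if (!col %in% names(df))
      rs_schema_error(what, sprintf("missing required column '%s'", col))
    type <- schema[[col]]
    if (type %in% c("numeric", "integer")) {
      val <- suppressWarnings(as.numeric(df[[col]]))
      if (anyNA(val) && !all(is.na(df[[col]]) == is.na(val)))
        rs_schema_error(what, sprintf("column '%s' is not %s", col, type))
      df[[col]] <- if (type == "integer") as.integer(val) else val
    } else {
      df[[col]] <- as.character(df[[col]])
    }
  }
  df
}

#' @rdname read_table
#' @export
schema_de <- function() c(gene_id = "character", base_mean = "numeric",
                          log2fc = "numeric", pvalue = "numeric",
                          padj = "numeric")

#' @rdname read_table
#' @export
schema_mirna_counts <- function() c(mirna_id = "character", count = "numeric")

#' @rdname read_table
#' @export
schema_growth <- function() c(day = "numeric", count = "numeric")

#' Write / read the differential-expression table
#'
#' The on-disk DE table carries only the observable columns (`gene_id`,
#' `base_mean`, `log2fc`, `pvalue`, `padj`); the simulator's `true_log2fc`
#' column is stripped on write so downstream stages never see the planted
#' truth.
#'
#' @param de DE data.frame.
#' @param path File path.
#' @return `write_de_table()` the path, invisibly; `read_de_table()` the
#'   validated data.frame.
#' @export
write_de_table <- function(de, path) {
  rs_write_tsv(de[, c("gene_id", "base_mean", "log2fc", "pvalue", "padj")], path)
}

#' @rdname write_de_table
#' @export
read_de_table <- function(path) read_table(path, schema_de(), "DE table")

#' Write / read miRNA profile files
#'
#' The miRNA profile is stored as a FASTA of RNA sequences plus a counts TSV
#' (`mirna_id`, `count`).
#'
#' @param mirnas miRNA data.frame from [simulate_mirna_profile()].
#' @param fasta_path,counts_path Output paths.
#' @return Paths (write) or the joined data.frame (read).
#' @export
write_mirna_profile <- function(mirnas, fasta_path, counts_path) {
  seqs <- Biostrings::RNAStringSet(mirnas$sequence)
  names(seqs) <- mirnas$mirna_id
  Biostrings::writeXStringSet(seqs, fasta_path)
  rs_write_tsv(mirnas[, c("mirna_id", "count")], counts_path)
  invisible(c(fasta_path, counts_path))
}

#' @rdname write_mirna_profile
#' @export
read_mirna_profile <- function(fasta_path, counts_path) {
  seqs <- Biostrings::readRNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  counts <- read_table(counts_path, schema_mirna_counts(), "miRNA counts")
  idx <- match(counts$mirna_id, ids)
  if (anyNA(idx))
    rs_schema_error("miRNA profile", "counts TSV contains ids absent from FASTA")
  data.frame(mirna_id = counts$mirna_id,
             sequence = as.character(seqs)[idx],
             count = counts$count, stringsAsFactors = FALSE)
}

#' Serialize planted truth to JSON
#'
#' Stores the site tables and gene sets of a `synthetic_truth` (the genome is
#' written separately as FASTA).
#'
#' @param truth A `synthetic_truth` object.
#' @param path JSON output path.
#' @return The path (write) or the reconstructed truth list (read; without the
#'   genome element).
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(ago_sites = truth$ago_sites, fam_sites = truth$fam_sites,
         cobound_genes = truth$cobound_genes,
         ago_only_genes = truth$ago_only_genes,
         nontarget_genes = truth$nontarget_genes,
         seed_motifs = truth$seed_motifs),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("cobound_genes", "ago_only_genes", "nontarget_genes"))
    x[[f]] <- as.character(unlist(x[[f]]))
  structure(x, class = "synthetic_truth")
}
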