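BED_HEADER <- paste("chrom", "start", "end", "name", "score", "strand",
                    "t2c_fraction", "mode_location", "conversion_count",
                    "feature_category", "read_count", sep = "\t")

#' Write / read called clusters as extended BED
#'
#' BED6 plus extension columns: `t2c_fraction`, `mode_location`,
#' `conversion_count`, `feature_category` (`"."` for unannotated clusters) and
#' `read_count`. The BED score is the read count capped at 1000 per the BED
#' spec; the uncapped count lives in the final extension column. An empty
#' cluster set writes a valid file holding only the header comment.
#'
#' @param clusters Cluster data.frame from [call_clusters()] (optionally
#'   annotated by [assign_clusters()]).
#' @param path Output path.
#' @return The path (write) or the cluster data.frame (read).
#' @export
write_clusters_bed <- function(clusters, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", BED_HEADER), con)
  if (is.null(clusters) || nrow(clusters) == 0L) return(invisible(path))
  feat <- if ("feature_category" %in% names(clusters))
    clusters$feature_category else rep(".", nrow(clusters))
  name <- if ("gene_id" %in% names(clusters) && any(!is.na(clusters$gene_id)))
    paste0(clusters$cluster_id, "|", ifelse(is.na(clusters$gene_id), ".",
                                            clusters$gene_id))
  else clusters$cluster_id
  df <- data.frame(
    chrom = clusters$chrom, start = clusters$start, end = clusters$end,
    name = name, score = pmin(clusters$read_count, 1000L),
    strand = clusters$strand,
    t2c_fraction = formatC(clusters$t2c_fraction, digits = 6, format = "f"),
    mode_location = clusters$mode_location,
    conversion_count = clusters$conversion_count,
    feature_category = ifelse(is.na(feat), ".", feat),
    read_count = clusters$read_count,
    stringsAsFactors = FALSE
  )
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_clusters_bed
#' @export
read_clusters_bed <- function(path) {
  if (!file.exists(path))
    rs_stop(sprintf("file not found: '%s'", path), "riscshift_io_error")
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  cols <- strsplit(BED_HEADER, "\t", fixed = TRUE)[[1]]
  if (length(lines) == 0L) {
    out <- data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(out) <- cols
    out$cluster_id <- character(0); out$gene_id <- character(0)
    return(out)
  }
  df <- read.delim(text = lines, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != length(cols))
    rs_schema_error("clusters BED", sprintf("expected %d columns, found %d",
                                            length(cols), ncol(df)))
  names(df) <- cols
  name_parts <- strsplit(df$name, "|", fixed = TRUE)
  df$cluster_id <- vapply(name_parts, `[`, character(1), 1L)
  df$gene_id <- vapply(name_parts, function(p)
    if (length(p) > 1L && p[2] != ".") p[2] else NA_character_, character(1))
  df$feature_category[df$feature_category == "."] <- NA_character_
  validate_interval(df$chrom, df$start, df$end, df$strand, "clusters BED")
  df
}
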