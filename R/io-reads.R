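#' Write aligned reads in the package TSV dialect
#'
#' Six columns: `read_id`, `chrom`, `start`, `end` (0-based half-open),
#' `strand`, `conversions` (comma-separated 0-based genomic positions of
#' T-to-C events on the read's sense strand; empty if none).
#'
#' @param reads Read data.frame (see [simulate_parclip_reads()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_reads_tsv <- function(reads, path) {
  validate_reads(reads)
  rs_write_tsv(reads[, c("read_id", "chrom", "start", "end", "strand",
                         "conversions")], path)
}

#' Read aligned PAR-CLIP reads
#'
#' Reads either the package TSV dialect or SAM. The dialect is sniffed from
#' the file extension unless given. SAM records are converted through BAM
#' (Rsamtools) in a temporary directory; unmapped and secondary records are
#' skipped with a message. Conversions are recovered from MD/NM tags: a
#' T-reference/C-read mismatch on a plus-strand alignment (A/G on minus) is a
#' T-to-C conversion; all other mismatches are counted in
#' `n_other_mismatches`.
#'
#' @param path Input path.
#' @param dialect `"auto"`, `"sam"` or `"tsv"`.
#' @return A validated read data.frame.
#' @export
read_alignments <- function(path, dialect = c("auto", "sam", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.sam(\\.gz)?$", path)) "sam" else "tsv"
  }
  if (dialect == "tsv") read_reads_tsv(path) else read_reads_sam(path)
}

read_reads_tsv <- function(path) {
  if (!file.exists(path))
    rs_stop(sprintf("file not found: '%s'", path), "riscshift_io_error")
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    rs_parse_error(path, 1L, "empty file")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("read_id", "chrom", "start", "end", "strand", "conversions")
  if (!all(need %in% header))
    rs_schema_error("reads TSV", paste("missing column:",
                                       paste(setdiff(need, header), collapse = ", ")))
  col <- match(need, header)
  n <- length(lines) - 1L
  out <- data.frame(read_id = character(n), chrom = character(n),
                    start = NA_integer_, end = NA_integer_,
                    strand = character(n), conversions = character(n),
                    n_other_mismatches = 0L, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1]]
    # an empty trailing conversions field is legal (strsplit drops it)
    if (length(f) == max(col) - 1L) f <- c(f, "")
    if (length(f) < max(col))
      rs_parse_error(path, lineno[i + 1L], "too few fields")
    st <- suppressWarnings(as.integer(f[col[3]]))
    en <- suppressWarnings(as.integer(f[col[4]]))
    if (is.na(st) || is.na(en))
      rs_parse_error(path, lineno[i + 1L], "non-integer coordinate")
    out$read_id[i] <- f[col[1]]; out$chrom[i] <- f[col[2]]
    out$start[i] <- st; out$end[i] <- en
    out$strand[i] <- f[col[5]]
    out$conversions[i] <- if (length(f) >= col[6]) f[col[6]] else ""
  }
  out$conversions[is.na(out$conversions)] <- ""
  validate_reads(out)
  out
}

# -- SAM ----------------------------------------------------------------------

#' Write aligned reads as SAM
#'
#' Emits one primary alignment per read with full-match CIGAR. Conversions are
#' encoded as reference mismatches in SEQ with consistent MD and NM tags: a
#' plus-strand read stores C where the reference has T at a conversion
#' position; a minus-strand read (FLAG 16, SEQ in plus orientation) stores G
#' where the reference has A.
#'
#' @param reads Read data.frame.
#' @param genome Named `DNAStringSet` reference (for SEQ and MD).
#' @param path Output SAM path.
#' @return The path, invisibly.
#' @export
write_reads_sam <- function(reads, genome, path) {
  validate_reads(reads)
  chrstr <- vapply(names(genome), function(nm) as.character(genome[[nm]]),
                   character(1))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                       vapply(chrstr, nchar, integer(1))),
               "@PG\tID:riscshift\tPN:riscshift"), con)
  conv <- parse_conversions(reads$conversions)
  recs <- vapply(seq_len(nrow(reads)), function(i) {
    s <- reads$start[i]; e <- reads$end[i]
    refseq <- substring(chrstr[[reads$chrom[i]]], s + 1L, e)
    seq <- refseq
    offs <- conv[[i]] - s
    sub <- if (reads$strand[i] == "+") "C" else "G"
    for (o in offs) substr(seq, o + 1L, o + 1L) <- sub
    md <- build_md(refseq, offs)
    paste(reads$read_id[i],
          if (reads$strand[i] == "-") 16L else 0L,
          reads$chrom[i], s + 1L, 255L, paste0(e - s, "M"),
          "*", 0L, 0L, seq, "*",
          sprintf("NM:i:%d", length(offs)), sprintf("MD:Z:%s", md),
          sep = "\t")
  }, character(1))
  writeLines(recs, con)
  invisible(path)
}

# MD tag for a full-match alignment with mismatches at 0-based offsets.
build_md <- function(refseq, offsets) {
  if (length(offsets) == 0L) return(as.character(nchar(refseq)))
  offsets <- sort(offsets)
  parts <- character(0)
  prev <- 0L
  for (o in offsets) {
    parts <- c(parts, as.character(o - prev), substr(refseq, o + 1L, o + 1L))
    prev <- o + 1L
  }
  paste0(paste(parts, collapse = ""), nchar(refseq) - prev)
}

read_reads_sam <- function(path) {
  if (!file.exists(path))
    rs_stop(sprintf("file not found: '%s'", path), "riscshift_io_error")
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam))
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = c("MD", "NM"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- b$flag
  skip <- bitwAnd(flag, 4L) > 0L | bitwAnd(flag, 256L) > 0L
  if (any(skip))
    message(sprintf("read_alignments: skipped %d unmapped/secondary SAM records",
                    sum(skip)))
  keep <- which(!skip)
  n <- length(keep)
  out <- data.frame(read_id = character(n), chrom = character(n),
                    start = NA_integer_, end = NA_integer_,
                    strand = character(n), conversions = character(n),
                    n_other_mismatches = 0L, stringsAsFactors = FALSE)
  seqs <- as.character(b$seq)
  for (j in seq_len(n)) {
    i <- keep[j]
    cig <- b$cigar[i]
    if (!grepl("^[0-9]+M$", cig))
      rs_validation_error(sprintf(
        "read '%s': unsupported CIGAR '%s' (full-match alignments only)",
        b$qname[i], cig))
    len <- as.integer(sub("M", "", cig, fixed = TRUE))
    minus <- bitwAnd(b$flag[i], 16L) > 0L
    s0 <- b$pos[i] - 1L
    mm <- parse_md(b$tag$MD[i])
    conv <- integer(0); other <- 0L
    for (k in seq_along(mm$offset)) {
      readbase <- substr(seqs[i], mm$offset[k] + 1L, mm$offset[k] + 1L)
      is_conv <- if (minus) mm$ref[k] == "A" && readbase == "G"
                 else mm$ref[k] == "T" && readbase == "C"
      if (is_conv) conv <- c(conv, s0 + mm$offset[k]) else other <- other + 1L
    }
    out$read_id[j] <- b$qname[i]
    out$chrom[j] <- as.character(b$rname[i])
    out$start[j] <- s0; out$end[j] <- s0 + len
    out$strand[j] <- if (minus) "-" else "+"
    out$conversions[j] <- paste(sort(conv), collapse = ",")
    out$n_other_mismatches[j] <- other
  }
  validate_reads(out)
  out
}

# Parse an MD tag of a gapless alignment into mismatch offsets and ref bases.
parse_md <- function(md) {
  if (is.na(md)) return(list(offset = integer(0), ref = character(0)))
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Z]+|[A-Z]", md))[[1]]
  off <- 0L; offset <- integer(0); ref <- character(0)
  for (t in toks) {
    if (grepl("^[0-9]+$", t)) {
      off <- off + as.integer(t)
    } else if (startsWith(t, "^")) {
      rs_validation_error("MD tag with deletion is unsupported")
    } else {
      offset <- c(offset, off); ref <- c(ref, t); off <- off + 1L
    }
  }
  list(offset = offset, ref = ref)
}
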