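#' @importFrom methods is
#' @importFrom stats median quantile rnorm rbinom rnbinom runif rlnorm p.adjust
#'   pnorm t.test lm coef setNames complete.cases
#' @importFrom utils read.delim write.table packageVersion head tail
NULL

# Internal: stop with a classed condition so callers/tests can match on class.
rs_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "riscshift_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

rs_config_error <- function(field, msg) {
  rs_stop(sprintf("invalid configuration: field '%s' %s", field, msg),
          "riscshift_config_error", field = field)
}

rs_schema_error <- function(what, msg) {
  rs_stop(sprintf("schema error in %s: %s", what, msg), "riscshift_schema_error")
}

rs_parse_error <- function(path, line, msg) {
  rs_stop(sprintf("parse error in '%s' at line %d: %s", path, line, msg),
          "riscshift_parse_error")
}

rs_validation_error <- function(msg) {
  rs_stop(msg, "riscshift_validation_error")
}

# Internal scalar checks used by the config validators.
is_count1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 1 && x == floor(x)
is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x <= 1
is_pos_real <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x > 0
is_nonneg_real <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0

check_field <- function(ok, field, msg) if (!ok) rs_config_error(field, msg)

# Derive a stage-specific RNG seed from the master seed; kept < 2^31.
derive_seed <- function(seed, stage_offset) {
  (as.integer(seed) + as.integer(stage_offset) * 10007L) %% 2147483647L
}

# 0-based half-open interval helpers ------------------------------------------

# All genomic coordinates in this package are 0-based half-open (BED-style).
# GRanges conversion adds 1 to the start.
as_granges0 <- function(chrom, start, end, strand = "*") {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = strand
  )
}

validate_interval <- function(chrom, start, end, strand, what = "interval") {
  if (any(is.na(chrom)) || any(is.na(start)) || any(is.na(end)))
    rs_validation_error(sprintf("%s: missing coordinate", what))
  if (any(start < 0) || any(start >= end))
    rs_validation_error(sprintf("%s: requires 0 <= start < end", what))
  if (!all(strand %in% c("+", "-")))
    rs_validation_error(sprintf("%s: strand must be '+' or '-'", what))
  invisible(TRUE)
}

# DNA/RNA alphabet helpers -----------------------------------------------------

DNA_BASES <- c("A", "C", "G", "T")

# Scalar-friendly reverse complement (plain string ops: the S4 container
# round-trip is far too heavy for per-site 6-mers).
revcomp_dna <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANTGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE), function(b)
    paste(rev(b), collapse = ""), character(1), USE.NAMES = FALSE)
}

rna_to_dna <- function(x) chartr("U", "T", x)
dna_to_rna <- function(x) chartr("T", "U", x)
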