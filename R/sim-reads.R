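#' Simulate PAR-CLIP reads with T-to-C conversion evidence
#'
#' Draws negative-binomial read counts per planted site, places 20-40 nt
#' footprint reads centred near each site's crosslink position, and marks
#' T-to-C conversions: a read covering the crosslink converts there with
#' probability `conversion_rate`, and every other covered sense-strand
#' reference T converts with probability `error_rate` (the sequencing-error
#' background). A configurable fraction of reads is scattered uniformly over
#' the genome as non-specific background carrying only error-level conversions.
#'
#' Conversion positions are genomic 0-based positions of the reference-sense T
#' (plus-strand A for minus-strand reads).
#'
#' @param truth A `synthetic_truth` from [plant_binding_sites()].
#' @param config A [sim_config()] object.
#' @param which `"ago"` or `"fam"`: which planted site set to sequence.
#' @return A data.frame of aligned reads with columns `read_id`, `chrom`,
#'   `start`, `end`, `strand`, `conversions` (comma-separated 0-based genomic
#'   positions, `""` if none) and `n_other_mismatches`.
#' @export
simulate_parclip_reads <- function(truth, config, which = c("ago", "fam")) {
  validate_sim_config(config)
  which <- match.arg(which)
  sites <- if (which == "ago") truth$ago_sites else truth$fam_sites
  set.seed(derive_seed(config$genome_seed, if (which == "ago") 5L else 6L))

  chrstr <- vapply(names(truth$genome), function(nm) {
    as.character(truth$genome[[nm]])
  }, character(1))
  # per-chromosome sorted 0-based positions of plus-strand T and A
  base_pos <- lapply(chrstr, function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    # doubles: findInterval would otherwise re-coerce on every lookup
    list(T = as.numeric(which(b == "T") - 1L),
         A = as.numeric(which(b == "A") - 1L))
  })
  sense_positions <- function(chrom, start, end, strand) {
    vec <- base_pos[[chrom]][[sense_base_for(strand)]]
    lo <- findInterval(start - 0.5, vec) + 1L
    hi <- findInterval(end - 0.5, vec)
    if (hi < lo) integer(0) else vec[lo:hi]
  }

  n_per_site <- rnbinom(nrow(sites), mu = config$reads_per_site_mean,
                        size = config$reads_per_site_dispersion)
  total_site <- sum(n_per_site)
  bf <- config$background_read_fraction
  n_bg <- if (bf > 0 && bf < 1) as.integer(round(total_site * bf / (1 - bf)))
          else if (bf == 0) 0L else total_site

  site_idx <- rep(seq_len(nrow(sites)), n_per_site)
  n_reads <- length(site_idx)
  len <- sample(config$read_length_min:config$read_length_max, n_reads + n_bg,
                replace = TRUE)
  jitter <- pmin(6L, pmax(-6L, as.integer(round(rnorm(n_reads, 0, 3)))))

  chrom_len <- vapply(chrstr, nchar, integer(1))
  rows <- vector("list", n_reads + n_bg)
  for (r in seq_len(n_reads)) {
    i <- site_idx[r]
    cx <- sites$crosslink_pos[i]
    s <- cx + jitter[r] - len[r] %/% 2L
    s <- max(0L, min(s, chrom_len[[sites$chrom[i]]] - len[r]))
    e <- s + len[r]
    conv <- integer(0)
    covers_cx <- cx >= s && cx < e
    if (covers_cx && runif(1) < config$conversion_rate) conv <- cx
    other_t <- setdiff(sense_positions(sites$chrom[i], s, e, sites$strand[i]), cx)
    if (length(other_t) && config$error_rate > 0) {
      hit <- runif(length(other_t)) < config$error_rate
      conv <- sort(c(conv, other_t[hit]))
    }
    rows[[r]] <- list(chrom = sites$chrom[i], start = s, end = e,
                      strand = sites$strand[i],
                      conversions = paste(conv, collapse = ","))
  }
  if (n_bg > 0L) {
    bg_chrom <- sample(names(chrstr), n_bg, replace = TRUE,
                       prob = chrom_len / sum(chrom_len))
    bg_strand <- sample(c("+", "-"), n_bg, replace = TRUE)
    for (r in seq_len(n_bg)) {
      L <- len[n_reads + r]
      s <- sample.int(chrom_len[[bg_chrom[r]]] - L, 1L) - 1L
      e <- s + L
      ts <- sense_positions(bg_chrom[r], s, e, bg_strand[r])
      conv <- if (length(ts) && config$error_rate > 0)
        ts[runif(length(ts)) < config$error_rate] else integer(0)
      rows[[n_reads + r]] <- list(chrom = bg_chrom[r], start = s, end = e,
                                  strand = bg_strand[r],
                                  conversions = paste(conv, collapse = ","))
    }
  }

  out <- data.frame(
    read_id = sprintf("r%06d", seq_along(rows)),
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    start = vapply(rows, `[[`, integer(1), "start"),
    end = vapply(rows, `[[`, integer(1), "end"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    conversions = vapply(rows, `[[`, character(1), "conversions"),
    n_other_mismatches = 0L,
    stringsAsFactors = FALSE
  )
  validate_reads(out)
  out
}

#' Validate an aligned-read table
#'
#' Checks the package's aligned-read invariants: 0-based half-open intervals,
#' strands in `{+, -}`, and every conversion position strictly inside its
#' read's span with positions sorted and distinct.
#'
#' @param reads A read data.frame (see [simulate_parclip_reads()]).
#' @return The input, invisibly, or an error describing the first violation.
#' @export
validate_reads <- function(reads) {
  need <- c("read_id", "chrom", "start", "end", "strand", "conversions")
  miss <- setdiff(need, names(reads))
  if (length(miss))
    rs_schema_error("reads", paste("missing column:", paste(miss, collapse = ", ")))
  validate_interval(reads$chrom, reads$start, reads$end, reads$strand, "read")
  conv <- parse_conversions(reads$conversions)
  bad <- which(vapply(seq_along(conv), function(i) {
    p <- conv[[i]]
    length(p) && (is.unsorted(p, strictly = TRUE) ||
                    any(p < reads$start[i]) || any(p >= reads$end[i]))
  }, logical(1)))
  if (length(bad))
    rs_validation_error(sprintf(
      "read '%s': conversion positions must be strictly increasing and within [start, end)",
      reads$read_id[bad[1]]))
  invisible(reads)
}

# Internal: comma-separated conversion strings -> list of integer vectors.
parse_conversions <- function(x) {
  lapply(strsplit(ifelse(is.na(x) | x == "", "", x), ",", fixed = TRUE),
         function(p) as.integer(p[nzchar(p)]))
}
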