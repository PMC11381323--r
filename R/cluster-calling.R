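#' Cluster-caller parameters
#'
#' @param min_reads Minimum reads overlapping a cluster interval (default 5).
#' @param min_conversion_locations Minimum distinct converted positions inside
#'   a cluster (default 1; clusters without conversion evidence are never
#'   emitted).
#' @param min_t2c_fraction Minimum fraction of a cluster's reads that carry a
#'   conversion inside it (default 0.1). This suppresses error-only clusters —
#'   at a per-base error rate of 1e-3 fewer than 1\% of reads carry a spurious
#'   conversion, an order of magnitude below the cut — while staying clear of
#'   the binomial noise of genuine sites: at a per-read conversion rate of 0.3
#'   and 20 reads, P(fraction < 0.1) is under 1\%, where a cut of 0.2 would
#'   discard more than a tenth of true sites.
#' @param kde_bandwidth Gaussian kernel bandwidth in nt (default 3).
#' @param merge_gap Maximum gap in nt between reads chained into one group
#'   (default 0: overlapping or bookended reads only).
#' @return A validated list of class `"caller_params"`.
#' @export
caller_params <- function(min_reads = 5L, min_conversion_locations = 1L,
                          min_t2c_fraction = 0.1, kde_bandwidth = 3,
                          merge_gap = 0L) {
  p <- list(min_reads = as.integer(min_reads),
            min_conversion_locations = as.integer(min_conversion_locations),
            min_t2c_fraction = min_t2c_fraction,
            kde_bandwidth = kde_bandwidth,
            merge_gap = as.integer(merge_gap))
  check_field(p$min_reads >= 0L, "min_reads", "must be non-negative")
  check_field(p$min_conversion_locations >= 0L, "min_conversion_locations",
              "must be non-negative")
  check_field(is_prob(p$min_t2c_fraction), "min_t2c_fraction",
              "must be in [0, 1]")
  check_field(is_pos_real(p$kde_bandwidth), "kde_bandwidth", "must be > 0")
  check_field(p$merge_gap >= 0L, "merge_gap", "must be non-negative")
  class(p) <- "caller_params"
  p
}

#' Group reads into overlap chains
#'
#' Partitions reads into maximal same-chromosome, same-strand groups whose
#' intervals form a connected chain with inter-read gaps of at most
#' `merge_gap` nt. Implemented by interval reduction (GenomicRanges); the test
#' suite checks it against a brute-force union-find oracle.
#'
#' @param reads Read data.frame.
#' @param merge_gap Maximum chained gap in nt.
#' @return The reads, sorted canonically, with an integer `group` column.
#' @export
group_reads <- function(reads, merge_gap = 0L) {
  validate_reads(reads)
  if (nrow(reads) == 0L) {
    reads$group <- integer(0)
    return(reads)
  }
  o <- order(reads$chrom, reads$strand, reads$start, reads$end, reads$read_id)
  reads <- reads[o, , drop = FALSE]
  rownames(reads) <- NULL
  gr <- as_granges0(reads$chrom, reads$start, reads$end, reads$strand)
  red <- GenomicRanges::reduce(gr, min.gapwidth = merge_gap + 1L)
  hits <- GenomicRanges::findOverlaps(gr, red, type = "within")
  group <- integer(nrow(reads))
  group[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  reads$group <- group
  reads
}

#' Call binding-site clusters from conversion evidence
#'
#' A desk-scale conversion-density caller in the spirit of PARalyzer: within
#' each read group, two normalised Gaussian kernel density estimates
#' (bandwidth `kde_bandwidth`) are computed — one over T-to-C conversion event
#' positions, one over sense-strand reference T positions covered by reads
#' without a conversion there. Cluster intervals are the maximal runs of
#' positions where the conversion density is at least the non-conversion
#' density (ties resolve toward conversion, favouring sensitivity). Each run
#' is scored and filtered on `min_reads`, `min_conversion_locations` and
#' `min_t2c_fraction`; the mode location is the position of maximum conversion
#' density (smallest coordinate on ties). The emitted cluster interval is the
#' region spanned by the run's supporting reads — the footprint-scale unit a
#' CLIP cluster represents — while the conversion statistics are computed on
#' the run itself. The output is deterministic and invariant under read input
#' order.
#'
#' @param reads Read data.frame.
#' @param genome Named `DNAStringSet` (needed to locate covered reference Ts).
#' @param params A [caller_params()] object.
#' @return A data.frame of clusters: `cluster_id`, `chrom`, `start`, `end`,
#'   `strand`, `read_count`, `conversion_count`, `n_conversion_locations`,
#'   `t2c_fraction`, `mode_location`.
#' @export
call_clusters <- function(reads, genome, params = caller_params()) {
  stopifnot(inherits(params, "caller_params"))
  empty <- data.frame(cluster_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), read_count = integer(0),
                      conversion_count = integer(0),
                      n_conversion_locations = integer(0),
                      t2c_fraction = numeric(0), mode_location = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(reads) || nrow(reads) == 0L) return(empty)
  grouped <- group_reads(reads, params$merge_gap)
  conv <- parse_conversions(grouped$conversions)

  base_pos <- lapply(stats::setNames(nm = unique(grouped$chrom)), function(nm) {
    b <- strsplit(as.character(genome[[nm]]), "", fixed = TRUE)[[1]]
    list(T = as.numeric(which(b == "T") - 1L),
         A = as.numeric(which(b == "A") - 1L))
  })
  sense_pos <- function(chrom, start, end, strand) {
    vec <- base_pos[[chrom]][[sense_base_for(strand)]]
    lo <- findInterval(start - 0.5, vec) + 1L
    hi <- findInterval(end - 0.5, vec)
    if (hi < lo) integer(0) else vec[lo:hi]
  }

  bw <- params$kde_bandwidth
  out <- list()
  for (g in split(seq_len(nrow(grouped)), grouped$group)) {
    conv_events <- unlist(conv[g], use.names = FALSE)
    if (length(conv_events) == 0L) next
    chrom <- grouped$chrom[g[1]]
    strand <- grouped$strand[g[1]]
    span <- c(min(grouped$start[g]), max(grouped$end[g]))
    nonconv_events <- unlist(lapply(g, function(i) {
      setdiff(sense_pos(chrom, grouped$start[i], grouped$end[i], strand),
              conv[[i]])
    }), use.names = FALSE)

    x <- span[1]:(span[2] - 1L)
    dens_conv <- colSums(matrix(stats::dnorm(outer(conv_events, x, "-"),
                                             sd = bw),
                                nrow = length(conv_events))) /
      length(conv_events)
    dens_non <- if (length(nonconv_events) == 0L) numeric(length(x)) else
      colSums(matrix(stats::dnorm(outer(nonconv_events, x, "-"), sd = bw),
                     nrow = length(nonconv_events))) / length(nonconv_events)

    runs <- rle(dens_conv >= dens_non)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      cs <- x[starts[k]]; ce <- x[ends[k]] + 1L
      in_run <- function(p) p >= cs & p < ce
      conv_in <- lapply(conv[g], function(p) p[in_run(p)])
      n_conv <- sum(lengths(conv_in))
      locs <- unique(unlist(conv_in, use.names = FALSE))
      supporting <- grouped$start[g] < ce & grouped$end[g] > cs
      rc <- sum(supporting)
      if (rc < params$min_reads) next
      if (length(locs) < params$min_conversion_locations) next
      t2c <- sum(lengths(conv_in[supporting]) > 0L) / rc
      if (t2c < params$min_t2c_fraction) next
      seg <- starts[k]:ends[k]
      mode <- x[seg[which.max(dens_conv[seg])]]
      # the emitted interval is the footprint-scale region spanned by the
      # supporting reads; the conversion-dominant run itself is narrower than
      # the protected footprint
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = min(grouped$start[g][supporting]),
        end = max(grouped$end[g][supporting]), strand = strand,
        read_count = rc, conversion_count = n_conv,
        n_conversion_locations = length(locs), t2c_fraction = t2c,
        mode_location = mode, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  cbind(cluster_id = sprintf("cl_%05d", seq_len(nrow(res))), res,
        stringsAsFactors = FALSE)
}
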