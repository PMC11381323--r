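sense_base_for <- function(strand) ifelse(strand == "+", "T", "A")

# 0-based genomic positions in [s+pad, e-pad) whose plus-strand base equals
# `sense_char`. Crosslink candidates are kept `pad` nt off the site edges so a
# seed motif window and the crosslink never collide.
inner_sense_positions <- function(chrstr, s, e, sense_char, pad = 4L) {
  if (e - s < 2L * pad + 1L) return(integer(0))
  sub <- substring(chrstr, s + pad + 1L, e - pad)
  idx <- which(strsplit(sub, "", fixed = TRUE)[[1]] == sense_char)
  s + pad + idx - 1L
}

nearest_to_mid <- function(positions, s, e) {
  positions[which.min(abs(positions - (s + e - 1) / 2))]
}

#' Plant AGO and FAM120A binding sites with exact overlap control
#'
#' Places exactly `n_ago_sites` AGO sites (70\% in 3'UTRs by default, mirroring
#' the 3'UTR-dominant occupancy of AGO CLIP data) and `n_fam_sites` FAM120A
#' sites on the simulated transcriptome. Exactly
#' `round(site_overlap_fraction * n_ago_sites)` AGO sites receive a same-strand
#' FAM site displaced by at most half a footprint (both proteins compete for
#' the same element, so designated pairs share most of their footprints); all
#' remaining FAM sites are placed on
#' genes without any AGO site, at least `site_margin` nt from other sites, so
#' the planted site-overlap fraction is exact by construction and gene-level
#' co-binding coincides with site-level overlap. Co-bound genes are chosen
#' uniformly among target genes (not in proportion to their site counts), so
#' the AGO-occupancy distributions of co-bound and AGO-only genes match.
#'
#' A 6mer seed-match motif (the DNA reverse complement of a top-ranked miRNA
#' seed) is written into the genome under `seed_match_fraction` of AGO sites,
#' placed so it never covers the site's crosslink position. Each site's
#' crosslink is the sense-strand reference T (plus-strand A for minus-strand
#' genes) nearest the site midpoint; candidate positions lacking such a base
#' are redrawn.
#'
#' @param models Transcript models from [generate_transcriptome()].
#' @param genome The matching genome `DNAStringSet`.
#' @param config A [sim_config()] object.
#' @param seed_motifs Character vector of DNA target motifs to plant; defaults
#'   to the seed motifs of the top 20 miRNAs from [simulate_mirna_profile()].
#' @return A list of class `"synthetic_truth"` with elements `ago_sites`,
#'   `fam_sites` (data.frames with coordinates, gene/feature labels, crosslink
#'   positions, overlap flags and planted motifs), the disjoint gene sets
#'   `cobound_genes`, `ago_only_genes`, `nontarget_genes`, and `genome` (the
#'   input genome with seed motifs written in).
#' @export
plant_binding_sites <- function(models, genome, config, seed_motifs = NULL) {
  validate_sim_config(config)
  if (is.null(seed_motifs)) {
    mir <- simulate_mirna_profile(config)
    seed_motifs <- vapply(head(mir$sequence, 20L),
                          function(s) extract_seed6(s)$target_motif_dna,
                          character(1), USE.NAMES = FALSE)
  }
  set.seed(derive_seed(config$genome_seed, 3L))
  w <- config$site_width
  margin <- config$site_margin
  chrstr <- vapply(as.character(names(genome)), function(nm) {
    as.character(genome[[nm]])
  }, character(1))

  gene_ids <- unique(models$gene_id)
  # plain-vector per-gene feature index (data.frame subsetting is too slow in
  # the placement loop)
  gsplit <- split(seq_len(nrow(models)), models$gene_id)
  feat_ix <- lapply(gsplit, function(ix) list(
    chrom = models$chrom[ix[1]], strand = models$strand[ix[1]],
    feature = models$feature[ix], start = models$start[ix],
    end = models$end[ix]))

  occupied <- new.env(parent = emptyenv())  # gene_id -> matrix(start, end)
  blocked <- function(g, s, e) {
    occ <- get0(g, envir = occupied)
    if (is.null(occ)) return(FALSE)
    any(s < occ[, 2] + margin & e > occ[, 1] - margin)
  }
  occupy <- function(g, s, e) {
    occ <- get0(g, envir = occupied)
    assign(g, rbind(occ, c(s, e)), envir = occupied)
  }

  bias_names <- names(config$feature_bias)
  place_site_in_gene <- function(g, classes) {
    fx <- feat_ix[[g]]
    sense <- sense_base_for(fx$strand)
    cseq <- chrstr[[fx$chrom]]
    for (cl in classes) {
      ri <- which(fx$feature == cl & (fx$end - fx$start) >= w)
      if (length(ri) == 0L) next
      for (try in seq_len(25L)) {
        r <- if (length(ri) == 1L) ri else ri[sample.int(length(ri), 1L)]
        starts <- fx$start[r]:(fx$end[r] - w)
        s <- starts[sample.int(length(starts), 1L)]
        e <- s + w
        if (blocked(g, s, e)) next
        if (length(inner_sense_positions(cseq, s, e, sense)) == 0L) next
        occupy(g, s, e)
        return(list(gene = g, chrom = fx$chrom, start = s, end = e,
                    strand = fx$strand, feature = cl))
      }
    }
    NULL
  }

  # fixed per-class quotas (largest-remainder split of the bias over n sites),
  # so the realized feature composition matches the bias exactly; a crowded
  # gene makes a site move to another gene, not to another feature class
  class_quota <- function(n) {
    cuts <- round(cumsum(config$feature_bias) * n)
    sample(rep(bias_names, diff(c(0L, cuts))))
  }

  place_all <- function(gene_vec, classes, what) {
    out <- vector("list", length(gene_vec))
    pool <- unique(gene_vec)
    for (i in seq_along(gene_vec)) {
      hit <- place_site_in_gene(gene_vec[i], classes[i])
      tries <- 0L
      while (is.null(hit) && tries < 100L) {
        hit <- place_site_in_gene(pool[sample.int(length(pool), 1L)],
                                  classes[i])
        tries <- tries + 1L
      }
      # last resort: keep the gene budget but relax the class
      if (is.null(hit))
        hit <- place_site_in_gene(gene_vec[i],
                                  sample(setdiff(bias_names, classes[i])))
      tries <- 0L
      while (is.null(hit) && tries < 100L) {
        hit <- place_site_in_gene(pool[sample.int(length(pool), 1L)],
                                  sample(bias_names))
        tries <- tries + 1L
      }
      if (is.null(hit))
        rs_stop(sprintf("insufficient gene space to place %s site %d of %d",
                        what, i, length(gene_vec)),
                "riscshift_capacity_error")
      out[[i]] <- hit
    }
    out
  }

  # -- AGO site placement ----------------------------------------------------
  n_ago <- config$n_ago_sites
  if (!is.null(config$n_target_genes)) {
    targets <- sample(gene_ids, config$n_target_genes)
    extra <- if (n_ago > length(targets))
      sample(targets, n_ago - length(targets), replace = TRUE) else character(0)
    gene_of_site <- c(targets, extra)
  } else {
    gene_of_site <- sample(gene_ids, n_ago, replace = TRUE)
  }
  ago_placed <- place_all(gene_of_site, class_quota(n_ago), "AGO")
  ago_gene <- vapply(ago_placed, `[[`, character(1), "gene")
  ago_chrom <- vapply(ago_placed, `[[`, character(1), "chrom")
  ago_start <- vapply(ago_placed, `[[`, integer(1), "start")
  ago_end <- vapply(ago_placed, `[[`, integer(1), "end")
  ago_strand <- vapply(ago_placed, `[[`, character(1), "strand")
  ago_feature <- vapply(ago_placed, `[[`, character(1), "feature")

  # -- designate overlapped AGO sites, choosing co-bound genes at gene level --
  k <- as.integer(round(config$site_overlap_fraction * n_ago))
  target_genes <- unique(ago_gene)
  overlapped <- logical(n_ago)
  cobound <- character(0)
  if (k > 0L) {
    remaining <- k
    idx_by_gene <- split(seq_len(n_ago), ago_gene)
    for (g in sample(target_genes)) {
      idx <- idx_by_gene[[g]]
      take <- min(length(idx), remaining)
      overlapped[idx[seq_len(take)]] <- TRUE
      cobound <- c(cobound, g)
      remaining <- remaining - take
      if (remaining == 0L) break
    }
  }

  # -- crosslinks and seed motifs for AGO sites ------------------------------
  n_motif <- as.integer(round(config$seed_match_fraction * n_ago))
  has_motif <- logical(n_ago)
  has_motif[sample.int(n_ago, n_motif)] <- TRUE
  crosslink <- integer(n_ago)
  seed_motif <- rep(NA_character_, n_ago)
  writes <- list()  # batched motif writes: (chrom, p0, text)
  for (i in seq_len(n_ago)) {
    sense <- sense_base_for(ago_strand[i])
    cand <- inner_sense_positions(chrstr[[ago_chrom[i]]], ago_start[i],
                                  ago_end[i], sense)
    cx <- nearest_to_mid(cand, ago_start[i], ago_end[i])
    crosslink[i] <- cx
    if (has_motif[i]) {
      cx_off <- cx - ago_start[i]
      a_all <- 0:(w - 6L)
      a_ok <- a_all[!(a_all >= cx_off - 5L & a_all <= cx_off)]
      a <- if (length(a_ok) == 1L) a_ok else a_ok[sample.int(length(a_ok), 1L)]
      motif <- if (length(seed_motifs) == 1L) seed_motifs else
        sample(seed_motifs, 1L)
      planted <- if (ago_strand[i] == "+") motif else revcomp_dna(motif)
      writes[[length(writes) + 1L]] <-
        list(chrom = ago_chrom[i], p0 = ago_start[i] + a, text = planted)
      seed_motif[i] <- motif
    }
  }
  # apply motif writes in one pass per chromosome (sites sit >= margin apart,
  # so windows never collide)
  if (length(writes)) {
    wchrom <- vapply(writes, `[[`, character(1), "chrom")
    for (cn in unique(wchrom)) {
      b <- strsplit(chrstr[[cn]], "", fixed = TRUE)[[1]]
      for (wr in writes[wchrom == cn]) {
        b[(wr$p0 + 1L):(wr$p0 + 6L)] <- strsplit(wr$text, "", fixed = TRUE)[[1]]
      }
      chrstr[[cn]] <- paste(b, collapse = "")
    }
  }

  ago <- data.frame(
    site_id = sprintf("ago_%04d", seq_len(n_ago)),
    chrom = ago_chrom, start = ago_start, end = ago_end, strand = ago_strand,
    gene_id = ago_gene, feature = ago_feature, crosslink_pos = crosslink,
    overlapped = overlapped, seed_motif = seed_motif, stringsAsFactors = FALSE)

  # -- FAM sites: paired (overlapping) then free (non-target genes) ----------
  pair_rows <- which(overlapped)
  n_pair <- length(pair_rows)
  n_fam <- config$n_fam_sites
  fam_chrom <- character(n_fam); fam_start <- integer(n_fam)
  fam_strand <- character(n_fam); fam_gene <- character(n_fam)
  fam_feature <- character(n_fam); fam_cx <- integer(n_fam)
  fam_pair <- rep(NA_character_, n_fam)
  # competition for the same element: a paired FAM footprint is displaced by
  # at most half a footprint, so designated pairs share >= w/2 - 2 nt
  deltas <- seq(-(w %/% 2L - 2L), w %/% 2L - 2L)
  for (j in seq_len(n_pair)) {
    i <- pair_rows[j]
    sense <- sense_base_for(ago_strand[i])
    cseq <- chrstr[[ago_chrom[i]]]
    fs <- NA_integer_; cx <- NA_integer_
    for (try in seq_len(50L)) {
      s <- ago_start[i] + deltas[sample.int(length(deltas), 1L)]
      cand <- inner_sense_positions(cseq, s, s + w, sense, pad = 2L)
      if (length(cand)) { fs <- s; cx <- nearest_to_mid(cand, s, s + w); break }
    }
    if (is.na(fs))
      rs_stop("could not place overlapping FAM site with a crosslink base",
              "riscshift_capacity_error")
    fx <- feat_ix[[ago_gene[i]]]
    mid <- fs + w %/% 2L
    hitf <- which(fx$start <= mid & mid < fx$end)
    fam_chrom[j] <- ago_chrom[i]; fam_start[j] <- fs
    fam_strand[j] <- ago_strand[i]; fam_gene[j] <- ago_gene[i]
    fam_feature[j] <- if (length(hitf)) fx$feature[hitf[1]] else ago_feature[i]
    fam_cx[j] <- cx; fam_pair[j] <- ago$site_id[i]
  }
  n_free <- n_fam - n_pair
  if (n_free > 0L) {
    free_pool <- setdiff(gene_ids, target_genes)
    if (length(free_pool) == 0L)
      rs_stop("no AGO-free genes left for non-overlapping FAM sites",
              "riscshift_capacity_error")
    free_genes <- free_pool[sample.int(length(free_pool), n_free,
                                       replace = TRUE)]
    free_placed <- place_all(free_genes, class_quota(n_free), "FAM")
    for (j in seq_len(n_free)) {
      h <- free_placed[[j]]
      sense <- sense_base_for(h$strand)
      cand <- inner_sense_positions(chrstr[[h$chrom]], h$start, h$end, sense,
                                    pad = 2L)
      if (length(cand) == 0L)
        rs_stop("free FAM site lacks a crosslink base", "riscshift_capacity_error")
      jj <- n_pair + j
      fam_chrom[jj] <- h$chrom; fam_start[jj] <- h$start
      fam_strand[jj] <- h$strand; fam_gene[jj] <- h$gene
      fam_feature[jj] <- h$feature
      fam_cx[jj] <- nearest_to_mid(cand, h$start, h$end)
    }
  }
  fam <- data.frame(
    site_id = sprintf("fam_%04d", seq_len(n_fam)),
    chrom = fam_chrom, start = fam_start, end = fam_start + w,
    strand = fam_strand, gene_id = fam_gene, feature = fam_feature,
    crosslink_pos = fam_cx, paired_ago = fam_pair, stringsAsFactors = FALSE)

  genome_out <- Biostrings::DNAStringSet(chrstr)
  names(genome_out) <- names(genome)

  structure(list(
    ago_sites = ago,
    fam_sites = fam,
    cobound_genes = sort(cobound),
    ago_only_genes = sort(setdiff(target_genes, cobound)),
    nontarget_genes = sort(setdiff(gene_ids, target_genes)),
    genome = genome_out,
    seed_motifs = seed_motifs
  ), class = "synthetic_truth")
}
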