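#' Simulate a differential-expression table with planted repression
#'
#' Generates the per-gene log2 fold-change table the RNAi analysis consumes.
#' The planted (true) effect follows the package's repression model:
#'
#' \deqn{lfc_{true}(g) = -\beta \cdot w(g) \cdot seed(g) \cdot
#'       (1 - \gamma \cdot cobound(g))}
#'
#' where `w(g)` is the gene's AGO occupancy weight (planted site count scaled
#' to a maximum of 1, so the most-bound gene has weight 1), `seed(g)` is 1 only
#' if at least one of the gene's AGO sites carries a planted 6mer seed motif,
#' and `cobound(g)` is 1 for genes whose AGO sites are co-bound by FAM120A.
#' Non-targets have true lfc 0. Observed lfc adds Gaussian noise with sd
#' `lfc_noise_sd`; p-values are the two-sided normal tail of observed lfc over
#' the noise sd, BH-adjusted across genes; base means are log-normal.
#'
#' @param truth A `synthetic_truth` from [plant_binding_sites()].
#' @param config A [sim_config()] object.
#' @return A data.frame with columns `gene_id`, `base_mean`, `log2fc`,
#'   `pvalue`, `padj` and `true_log2fc` (the planted effect; dropped by
#'   [write_de_table()] so downstream stages cannot see it).
#' @export
simulate_expression_changes <- function(truth, config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$genome_seed, 4L))
  genes <- sort(unique(c(truth$cobound_genes, truth$ago_only_genes,
                         truth$nontarget_genes)))
  n_sites <- table(truth$ago_sites$gene_id)
  sites_of <- as.integer(n_sites[genes])
  sites_of[is.na(sites_of)] <- 0L
  seed_genes <- unique(truth$ago_sites$gene_id[!is.na(truth$ago_sites$seed_motif)])
  seed_flag <- as.integer(genes %in% seed_genes)
  cobound_flag <- as.integer(genes %in% truth$cobound_genes)

  max_sites <- max(sites_of, 1L)
  w <- sites_of / max_sites
  true_lfc <- -config$repression_beta * w * seed_flag *
    (1 - config$stabilization_gamma * cobound_flag)

  sd <- config$lfc_noise_sd
  obs <- true_lfc + if (sd > 0) rnorm(length(genes), 0, sd) else 0
  pval <- if (sd > 0) 2 * pnorm(-abs(obs) / sd) else as.numeric(obs == 0)
  data.frame(
    gene_id = genes,
    base_mean = rlnorm(length(genes), config$base_mean_meanlog,
                       config$base_mean_sdlog),
    log2fc = obs,
    pvalue = pval,
    padj = p.adjust(pval, method = "BH"),
    true_log2fc = true_lfc,
    stringsAsFactors = FALSE
  )
}

#' Recompute planted log2 fold changes from truth labels
#'
#' Independent reimplementation of the repression formula used by
#' [simulate_expression_changes()], driven purely by the truth object's site
#' table and gene sets. Exists so tests can verify the planted effect is a pure
#' function of the truth labels.
#'
#' @inheritParams simulate_expression_changes
#' @return Named numeric vector of true log2 fold changes per gene.
#' @export
true_lfc_from_truth <- function(truth, config) {
  genes <- sort(unique(c(truth$cobound_genes, truth$ago_only_genes,
                         truth$nontarget_genes)))
  out <- setNames(numeric(length(genes)), genes)
  tab <- truth$ago_sites
  if (nrow(tab) == 0L) return(out)
  counts <- vapply(genes, function(g) sum(tab$gene_id == g), integer(1))
  mx <- max(counts, 1L)
  for (g in genes) {
    has_seed <- any(!is.na(tab$seed_motif[tab$gene_id == g]))
    out[g] <- -config$repression_beta * (sum(tab$gene_id == g) / mx) *
      as.numeric(has_seed) *
      (1 - config$stabilization_gamma * (g %in% truth$cobound_genes))
  }
  out
}
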