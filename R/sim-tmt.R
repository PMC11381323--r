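#' Simulate a TMT protein quantification table
#'
#' Builds a log2-intensity table with KO and WT replicate channels. A planted
#' subset of proteins carries a mean KO-WT log2 shift of `tmt_shift`
#' (>= log2(1.5) under the defaults), against per-replicate Gaussian noise of
#' sd `tmt_noise_sd`; the generator refuses degenerate zero-variance input.
#'
#' @param config A [sim_config()] object.
#' @return A list with `quant` (data.frame: `protein_id`, `ko_1..`, `wt_1..`)
#'   and `enriched_proteins` (ids of the planted enriched subset).
#' @export
simulate_tmt_table <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$genome_seed, 7L))
  n <- config$tmt_n_proteins
  ids <- sprintf("prot_%04d", seq_len(n))
  enriched <- sort(sample(ids, config$tmt_n_enriched))
  base <- rnorm(n, mean = 20, sd = 2)
  shift <- ifelse(ids %in% enriched, config$tmt_shift, 0)
  ko <- sapply(seq_len(config$tmt_n_ko), function(j)
    base + shift + rnorm(n, 0, config$tmt_noise_sd))
  wt <- sapply(seq_len(config$tmt_n_wt), function(j)
    base + rnorm(n, 0, config$tmt_noise_sd))
  colnames(ko) <- sprintf("ko_%d", seq_len(config$tmt_n_ko))
  colnames(wt) <- sprintf("wt_%d", seq_len(config$tmt_n_wt))
  list(
    quant = data.frame(protein_id = ids, ko, wt, stringsAsFactors = FALSE),
    enriched_proteins = enriched
  )
}

#' Simulate growth-curve counts
#'
#' Cell counts under Malthusian growth `N(t) = N0 * exp(k t)` observed daily
#' with multiplicative log-normal noise, in four replicate series (matching a
#' typical proliferation-assay design).
#'
#' @param config A [sim_config()] object.
#' @param n_replicates Number of replicate growth series.
#' @return A data.frame with columns `replicate`, `day`, `count`.
#' @export
simulate_growth_counts <- function(config, n_replicates = 4L) {
  validate_sim_config(config)
  set.seed(derive_seed(config$genome_seed, 8L))
  days <- 0:config$growth_days
  out <- expand.grid(replicate = seq_len(n_replicates), day = days,
                     KEEP.OUT.ATTRS = FALSE)
  out <- out[order(out$replicate, out$day), ]
  mu <- config$growth_n0 * exp(config$growth_rate * out$day)
  noise <- if (config$growth_noise_sd > 0)
    exp(rnorm(nrow(out), 0, config$growth_noise_sd)) else 1
  out$count <- mu * noise
  rownames(out) <- NULL
  out
}
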