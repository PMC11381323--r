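#' Simulate a miRNA expression profile
#'
#' Draws `n_mirnas` random 21-22 nt RNA sequences and assigns read counts
#' following a Zipf law with the configured exponent, so that abundance is
#' concentrated in the top-ranked miRNAs the way AGO-bound miRNA profiles are
#' (a few hundred species carry almost all reads). Counts are non-increasing
#' with rank by construction; the top-ranked sequences are the ones whose seed
#' motifs [plant_binding_sites()] writes under planted AGO sites.
#'
#' @param config A [sim_config()] object.
#' @return A data.frame with columns `mirna_id`, `sequence` (RNA alphabet) and
#'   `count`, ordered by decreasing count.
#' @export
simulate_mirna_profile <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$genome_seed, 2L))
  n <- config$n_mirnas
  len <- sample(21:22, n, replace = TRUE)
  seqs <- vapply(len, function(L) {
    paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
  }, character(1))
  counts <- pmax(1L, as.integer(round(
    1e6 * seq_len(n)^(-config$mirna_zipf_exponent)
  )))
  data.frame(
    mirna_id = sprintf("mir-%04d", seq_len(n)),
    sequence = seqs,
    count = counts,
    stringsAsFactors = FALSE
  )
}
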