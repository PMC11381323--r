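#' Simulation configuration
#'
#' Builds the validated configuration object that drives every synthetic-data
#' generator in the package. The defaults define the package's reference study
#' conditions: a toy transcriptome of protein-coding genes, AGO binding sites
#' concentrated in 3'UTRs, PAR-CLIP coverage with a strong T-to-C conversion
#' signal over a small sequencing-error background, a heavy-tailed miRNA
#' abundance profile, and planted repression that scales with AGO occupancy and
#' is attenuated on co-bound genes by a stabilization factor.
#'
#' @param n_genes Number of genes in the toy transcriptome (>= 2).
#' @param genome_seed Master RNG seed; every generator derives its stream from
#'   it, so identical configs give byte-identical outputs.
#' @param n_ago_sites,n_fam_sites Numbers of planted AGO and FAM120A binding
#'   sites.
#' @param site_overlap_fraction Fraction rho of AGO sites overlapped (>= 1 nt,
#'   same strand) by a FAM site; the planted overlap count is exactly
#'   `round(rho * n_ago_sites)`.
#' @param n_target_genes Optional number of distinct genes carrying AGO sites;
#'   `NULL` lets site-to-gene assignment fall where it may.
#' @param reads_per_site_mean,reads_per_site_dispersion Negative-binomial mean
#'   and size for per-site read counts (size -> Inf approaches Poisson).
#' @param conversion_rate Probability that a read covering a site's crosslink
#'   position carries a T-to-C conversion there.
#' @param error_rate Per-base background conversion probability at every other
#'   covered reference T.
#' @param background_read_fraction Fraction of simulated reads placed uniformly
#'   over the genome rather than at planted sites.
#' @param repression_beta Maximum planted log2FC repression magnitude (>= 0).
#' @param stabilization_gamma Attenuation of repression on co-bound genes, in
#'   \[0, 1\]; 1 means full protection.
#' @param lfc_noise_sd Standard deviation of Gaussian noise added to planted
#'   log2 fold changes.
#' @param n_mirnas Number of simulated miRNAs.
#' @param mirna_zipf_exponent Zipf exponent (> 1) of the miRNA abundance law.
#' @param seed_match_fraction Fraction of planted AGO sites that receive a 6mer
#'   seed-match motif written into the genome.
#' @param site_width Width in nt of planted binding sites.
#' @param read_length_min,read_length_max PAR-CLIP footprint length range in nt.
#' @param feature_bias Named probabilities over
#'   `c("three_utr", "cds", "intron", "five_utr")` for AGO site placement;
#'   the default puts 70\% of sites in 3'UTRs.
#' @param site_margin Minimum separation in nt between planted sites that are
#'   not a designated AGO/FAM overlap pair.
#' @param genes_per_chrom Genes per simulated chromosome.
#' @param intergenic_gap_min Minimum intergenic gap in nt.
#' @param base_mean_meanlog,base_mean_sdlog Log-normal parameters of the DE
#'   table's base-mean column.
#' @param tmt_n_proteins,tmt_n_enriched,tmt_n_ko,tmt_n_wt,tmt_shift,tmt_noise_sd
#'   TMT proteomics simulation: table size, planted enriched-set size,
#'   replicates per group, planted KO-WT log2 shift (>= log2(1.5)) and
#'   replicate noise sd (> 0).
#' @param growth_n0,growth_rate,growth_days,growth_noise_sd Growth-curve
#'   simulation: initial count, Malthusian rate per day, duration, and
#'   multiplicative log-normal noise sd.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 1000L,
                       genome_seed = 1L,
                       n_ago_sites = 400L,
                       n_fam_sites = 400L,
                       site_overlap_fraction = 0.65,
                       n_target_genes = NULL,
                       reads_per_site_mean = 20,
                       reads_per_site_dispersion = 10,
                       conversion_rate = 0.3,
                       error_rate = 0.001,
                       background_read_fraction = 0.05,
                       repression_beta = 0.5,
                       stabilization_gamma = 0.8,
                       lfc_noise_sd = 0.2,
                       n_mirnas = 500L,
                       mirna_zipf_exponent = 1.1,
                       seed_match_fraction = 0.8,
                       site_width = 24L,
                       read_length_min = 20L,
                       read_length_max = 40L,
                       feature_bias = c(three_utr = 0.70, cds = 0.15,
                                        intron = 0.10, five_utr = 0.05),
                       site_margin = 100L,
                       genes_per_chrom = 25L,
                       intergenic_gap_min = 500L,
                       base_mean_meanlog = 5,
                       base_mean_sdlog = 1.5,
                       tmt_n_proteins = 500L,
                       tmt_n_enriched = 50L,
                       tmt_n_ko = 3L,
                       tmt_n_wt = 3L,
                       tmt_shift = 1.0,
                       tmt_noise_sd = 0.1,
                       growth_n0 = 3125,
                       growth_rate = 0.55,
                       growth_days = 6L,
                       growth_noise_sd = 0.05) {
  cfg <- list(
    n_genes = as.integer(n_genes), genome_seed = as.integer(genome_seed),
    n_ago_sites = as.integer(n_ago_sites), n_fam_sites = as.integer(n_fam_sites),
    site_overlap_fraction = site_overlap_fraction,
    n_target_genes = if (is.null(n_target_genes)) NULL else as.integer(n_target_genes),
    reads_per_site_mean = reads_per_site_mean,
    reads_per_site_dispersion = reads_per_site_dispersion,
    conversion_rate = conversion_rate, error_rate = error_rate,
    background_read_fraction = background_read_fraction,
    repression_beta = repression_beta,
    stabilization_gamma = stabilization_gamma,
    lfc_noise_sd = lfc_noise_sd,
    n_mirnas = as.integer(n_mirnas),
    mirna_zipf_exponent = mirna_zipf_exponent,
    seed_match_fraction = seed_match_fraction,
    site_width = as.integer(site_width),
    read_length_min = as.integer(read_length_min),
    read_length_max = as.integer(read_length_max),
    feature_bias = feature_bias,
    site_margin = as.integer(site_margin),
    genes_per_chrom = as.integer(genes_per_chrom),
    intergenic_gap_min = as.integer(intergenic_gap_min),
    base_mean_meanlog = base_mean_meanlog, base_mean_sdlog = base_mean_sdlog,
    tmt_n_proteins = as.integer(tmt_n_proteins),
    tmt_n_enriched = as.integer(tmt_n_enriched),
    tmt_n_ko = as.integer(tmt_n_ko), tmt_n_wt = as.integer(tmt_n_wt),
    tmt_shift = tmt_shift, tmt_noise_sd = tmt_noise_sd,
    growth_n0 = growth_n0, growth_rate = growth_rate,
    growth_days = as.integer(growth_days), growth_noise_sd = growth_noise_sd
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param config A `sim_config` object to re-validate.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with(config, {
    check_field(is_count1(n_genes) && n_genes >= 2, "n_genes", "must be an integer >= 2")
    check_field(is.numeric(genome_seed) && length(genome_seed) == 1L &&
                  !is.na(genome_seed), "genome_seed", "must be a single integer")
    check_field(is_count1(n_ago_sites), "n_ago_sites", "must be a positive integer")
    check_field(is_count1(n_fam_sites), "n_fam_sites", "must be a positive integer")
    check_field(is_prob(site_overlap_fraction), "site_overlap_fraction",
                "must be in [0, 1]")
    check_field(round(site_overlap_fraction * n_ago_sites) <= n_fam_sites,
                "site_overlap_fraction",
                "requires rho * n_ago_sites <= n_fam_sites")
    if (!is.null(n_target_genes))
      check_field(is_count1(n_target_genes) && n_target_genes <= n_genes &&
                    n_target_genes <= n_ago_sites, "n_target_genes",
                  "must be a positive integer <= min(n_genes, n_ago_sites)")
    check_field(is_pos_real(reads_per_site_mean), "reads_per_site_mean",
                "must be a positive real")
    check_field(is_pos_real(reads_per_site_dispersion), "reads_per_site_dispersion",
                "must be a positive real")
    check_field(is_prob(conversion_rate), "conversion_rate", "must be in [0, 1]")
    check_field(is_prob(error_rate), "error_rate", "must be in [0, 1]")
    check_field(is_prob(background_read_fraction), "background_read_fraction",
                "must be in [0, 1]")
    check_field(is_nonneg_real(repression_beta), "repression_beta",
                "must be a non-negative real")
    check_field(is_prob(stabilization_gamma), "stabilization_gamma",
                "must be in [0, 1]")
    check_field(is_nonneg_real(lfc_noise_sd), "lfc_noise_sd",
                "must be a non-negative real")
    check_field(is_count1(n_mirnas), "n_mirnas", "must be a positive integer")
    check_field(is.numeric(mirna_zipf_exponent) && mirna_zipf_exponent > 1,
                "mirna_zipf_exponent", "must be > 1")
    check_field(is_prob(seed_match_fraction), "seed_match_fraction",
                "must be in [0, 1]")
    check_field(is_count1(site_width) && site_width >= 10, "site_width",
                "must be an integer >= 10")
    check_field(is_count1(read_length_min) && is_count1(read_length_max) &&
                  read_length_min <= read_length_max, "read_length_min",
                "requires read_length_min <= read_length_max")
    check_field(is.numeric(feature_bias) &&
                  setequal(names(feature_bias),
                           c("three_utr", "cds", "intron", "five_utr")) &&
                  all(feature_bias >= 0) &&
                  abs(sum(feature_bias) - 1) < 1e-8, "feature_bias",
                "must be probabilities over three_utr/cds/intron/five_utr summing to 1")
    check_field(is_count1(genes_per_chrom), "genes_per_chrom",
                "must be a positive integer")
    check_field(is_count1(intergenic_gap_min), "intergenic_gap_min",
                "must be a positive integer")
    check_field(is_count1(tmt_n_proteins), "tmt_n_proteins",
                "must be a positive integer")
    check_field(is_count1(tmt_n_enriched) && tmt_n_enriched <= tmt_n_proteins,
                "tmt_n_enriched", "must be a positive integer <= tmt_n_proteins")
    check_field(is_count1(tmt_n_ko) && tmt_n_ko >= 2, "tmt_n_ko",
                "must be an integer >= 2")
    check_field(is_count1(tmt_n_wt) && tmt_n_wt >= 2, "tmt_n_wt",
                "must be an integer >= 2")
    check_field(is_nonneg_real(tmt_shift), "tmt_shift",
                "must be a non-negative real")
    check_field(is_pos_real(tmt_noise_sd), "tmt_noise_sd", "must be > 0")
    check_field(is_pos_real(growth_n0), "growth_n0", "must be positive")
    check_field(is.numeric(growth_rate) && length(growth_rate) == 1L,
                "growth_rate", "must be a single real")
    check_field(is_count1(growth_days) && growth_days >= 2, "growth_days",
                "must be an integer >= 2")
    check_field(is_nonneg_real(growth_noise_sd), "growth_noise_sd",
                "must be a non-negative real")
  })
  config
}

#' @export
print.sim_config <- function(x, ...) {
  cat("riscshift simulation config\n")
  cat(sprintf("  genes: %d  AGO sites: %d  FAM sites: %d  rho: %.2f\n",
              x$n_genes, x$n_ago_sites, x$n_fam_sites, x$site_overlap_fraction))
  cat(sprintf("  reads/site NB(%.1f, size %.1f), conversion %.3f, error %.4f\n",
              x$reads_per_site_mean, x$reads_per_site_dispersion,
              x$conversion_rate, x$error_rate))
  cat(sprintf("  beta %.2f  gamma %.2f  lfc noise %.2f  seed-match %.2f\n",
              x$repression_beta, x$stabilization_gamma, x$lfc_noise_sd,
              x$seed_match_fraction))
  invisible(x)
}
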