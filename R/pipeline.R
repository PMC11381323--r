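#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis: the simulation knobs, the
#' cluster-caller parameters, the seed-filter settings, the occupancy bins,
#' the co-binding split and the ancillary thresholds. Unknown arguments are
#' rejected.
#'
#' @param sim A [sim_config()].
#' @param caller A [caller_params()].
#' @param simulate Generate all inputs (`TRUE`, default) or read them from
#'   `inputs`.
#' @param inputs Named list of input paths for `simulate = FALSE` mode
#'   (`genome`, `annotation`, `reads_ago`, `reads_fam`, `mirna_fasta`,
#'   `mirna_counts`, `de`).
#' @param top_n_mirnas Expressed-miRNA cut for the seed set (default 200).
#' @param seed_flank Flank in nt around cluster intervals scanned for seed
#'   matches (default 10).
#' @param bins Occupancy percentile bins (see [bin_targets()]).
#' @param split_percentile Co-binding occupancy split (default 25).
#' @param min_count,min_samples Expression floor (defaults 10 and 3).
#' @param padj_threshold,lfc_threshold DE thresholds (defaults 0.01, 0.5).
#' @param fc_threshold,p_threshold TMT enrichment thresholds (defaults 1.5,
#'   0.075).
#' @param seed Overrides `sim$genome_seed` when given.
#' @param ... Unknown keys; any use is an error.
#' @return A validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = sim_config(), caller = caller_params(),
                            simulate = TRUE, inputs = list(),
                            top_n_mirnas = 200L, seed_flank = 10L,
                            bins = list(top_5_20 = c(5, 20),
                                        mid_25_100 = c(25, 100)),
                            split_percentile = 25,
                            min_count = 10, min_samples = 3,
                            padj_threshold = 0.01, lfc_threshold = 0.5,
                            fc_threshold = 1.5, p_threshold = 0.075,
                            seed = NULL, ...) {
  extra <- list(...)
  if (length(extra))
    rs_config_error(names(extra)[1], "is not a recognized pipeline setting")
  if (!is.null(seed)) {
    sim$genome_seed <- as.integer(seed)
    sim <- validate_sim_config(sim)
  }
  stopifnot(inherits(sim, "sim_config"), inherits(caller, "caller_params"))
  check_field(is_count1(top_n_mirnas), "top_n_mirnas", "must be a positive integer")
  check_field(is_count1(seed_flank + 1), "seed_flank", "must be a non-negative integer")
  check_field(is.list(bins) && length(bins) >= 1 && !is.null(names(bins)),
              "bins", "must be a named list of percentile pairs")
  for (nm in names(bins))
    check_field(length(bins[[nm]]) == 2 && bins[[nm]][1] < bins[[nm]][2] &&
                  bins[[nm]][1] >= 0 && bins[[nm]][2] <= 100,
                "bins", sprintf("bin '%s' must be c(lo, hi) within [0, 100]", nm))
  check_field(is.numeric(split_percentile) && split_percentile > 0 &&
                split_percentile < 100, "split_percentile", "must be in (0, 100)")
  structure(list(sim = sim, caller = caller, simulate = isTRUE(simulate),
                 inputs = inputs, top_n_mirnas = as.integer(top_n_mirnas),
                 seed_flank = as.integer(seed_flank), bins = bins,
                 split_percentile = split_percentile, min_count = min_count,
                 min_samples = min_samples, padj_threshold = padj_threshold,
                 lfc_threshold = lfc_threshold, fc_threshold = fc_threshold,
                 p_threshold = p_threshold),
            class = "pipeline_config")
}

#' Run the end-to-end analysis
#'
#' Executes simulate -> cluster calling -> feature annotation -> seed filter
#' -> RNAi cumulative-distribution analysis -> co-binding/stabilization ->
#' ancillary statistics, writing all intermediate artifacts (FASTA, TSV, SAM,
#' BED, JSON) under `out_dir` and returning the consolidated report. The run
#' is fully deterministic given the config's seed: two runs with the same
#' config produce byte-identical `report.json` files. A stage failure is
#' re-raised with the stage name after a `MANIFEST` recording the completed
#' stages is written.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The report, invisibly (also written to `out_dir/report.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inp <- file.path(out_dir, "inputs")
  dir.create(inp, showWarnings = FALSE)
  done <- character(0)
  note_done <- function(stage) done <<- c(done, stage)
  write_manifest <- function(complete) {
    writeLines(c(sprintf("complete: %s", tolower(complete)),
                 paste("stage:", done)),
               file.path(out_dir, "MANIFEST"))
  }
  stage <- function(name, expr) {
    tryCatch({ v <- force(expr); note_done(name); v },
             error = function(e) {
               write_manifest(FALSE)
               rs_stop(sprintf("%s: %s", name, conditionMessage(e)),
                       "riscshift_stage_error")
             })
  }
  need_input <- function(key) {
    p <- config$inputs[[key]]
    if (is.null(p) || !file.exists(p))
      stop(sprintf("missing input '%s'", key), call. = FALSE)
    p
  }
  report <- list(package = "riscshift",
                 version = as.character(packageVersion("riscshift")),
                 seed = config$sim$genome_seed,
                 config = config_echo(config))

  if (config$simulate) {
    sim <- stage("simulate", {
      tx <- generate_transcriptome(config$sim)
      mirnas <- simulate_mirna_profile(config$sim)
      truth <- plant_binding_sites(tx$models, tx$genome, config$sim)
      reads_ago <- simulate_parclip_reads(truth, config$sim, "ago")
      reads_fam <- simulate_parclip_reads(truth, config$sim, "fam")
      de <- simulate_expression_changes(truth, config$sim)
      tmt <- simulate_tmt_table(config$sim)
      growth <- simulate_growth_counts(config$sim)
      write_genome_fasta(truth$genome, file.path(inp, "genome.fa"))
      write_annotation(tx$models, file.path(inp, "annotation.tsv"))
      export_gtf(tx$models, file.path(inp, "annotation.gtf"))
      write_reads_tsv(reads_ago, file.path(inp, "reads_ago.tsv"))
      write_reads_sam(reads_ago, truth$genome, file.path(inp, "reads_ago.sam"))
      write_reads_tsv(reads_fam, file.path(inp, "reads_fam.tsv"))
      write_mirna_profile(mirnas, file.path(inp, "mirna.fa"),
                          file.path(inp, "mirna_counts.tsv"))
      write_de_table(de, file.path(inp, "de.tsv"))
      rs_write_tsv(tmt$quant, file.path(inp, "tmt.tsv"))
      rs_write_tsv(growth, file.path(inp, "growth.tsv"))
      write_truth_json(truth, file.path(inp, "truth.json"))
      list(genome = truth$genome, models = tx$models, mirnas = mirnas,
           truth = truth, reads_ago = reads_ago, reads_fam = reads_fam,
           de = de, tmt = tmt$quant, growth = growth)
    })
  } else {
    sim <- stage("load_inputs", {
      genome <- read_genome_fasta(need_input("genome"))
      models <- read_annotation(need_input("annotation"))
      list(genome = genome, models = models,
           mirnas = read_mirna_profile(need_input("mirna_fasta"),
                                       need_input("mirna_counts")),
           truth = NULL,
           reads_ago = read_alignments(need_input("reads_ago")),
           reads_fam = read_alignments(need_input("reads_fam")),
           de = NULL, tmt = NULL, growth = NULL)
    })
  }

  clusters <- stage("call_clusters", {
    ago <- call_clusters(sim$reads_ago, sim$genome, config$caller)
    fam <- call_clusters(sim$reads_fam, sim$genome, config$caller)
    list(ago = ago, fam = fam)
  })

  annotated <- stage("annotate", {
    ago <- assign_clusters(clusters$ago, sim$models)
    fam <- assign_clusters(clusters$fam, sim$models)
    write_clusters_bed(ago, file.path(out_dir, "clusters_ago.bed"))
    write_clusters_bed(fam, file.path(out_dir, "clusters_fam.bed"))
    dist <- summarize_read_distribution(sim$reads_ago, ago)
    rs_write_tsv(dist, file.path(out_dir, "read_distribution_ago.tsv"))
    list(ago = ago, fam = fam, read_distribution = dist)
  })

  seeds <- stage("seeds", {
    set <- select_top_mirnas(compute_rpm(sim$mirnas), config$top_n_mirnas)
    seqs <- site_sequences(annotated$ago, sim$genome, config$seed_flank)
    matches <- scan_seed_matches(seqs, set)
    per_gene <- aggregate_seed_matches(annotated$ago, matches)
    rs_write_tsv(cbind(annotated$ago[, c("cluster_id", "gene_id")], matches),
                 file.path(out_dir, "seed_matches.tsv"))
    list(set = set, matches = matches, per_gene = per_gene)
  })

  rnai <- stage("rnai", {
    if (is.null(sim$de)) sim$de <- read_de_table(need_input("de"))
    expressed <- filter_expressed(sim$de, config$min_count, config$min_samples)
    profiles <- build_profiles(gene_site_counts(annotated$ago),
                               seeds$per_gene, sim$de, expressed)
    profiles <- bin_targets(profiles, config$bins)
    comp <- compare_ecdfs(profiles)
    rs_write_tsv(as.data.frame(profiles), file.path(out_dir, "profiles.tsv"))
    rs_write_tsv(attr(comp, "curves"), file.path(out_dir, "ecdf_curves.tsv"))
    list(profiles = profiles, comparisons = comp)
  })

  cobind <- stage("cobind", {
    summ <- estimate_site_overlap_from_clusters(
      annotated$ago, annotated$fam, footprint = config$sim$site_width)
    raw <- compute_site_overlap(annotated$ago, annotated$fam)
    summ$raw_cluster_overlap_fraction <- raw$site_overlap_fraction
    stab <- tryCatch(
      stabilization_analysis(summ, rnai$profiles, config$split_percentile),
      riscshift_validation_error = function(e) NULL)
    list(summary = summ, stabilization = stab)
  })

  ancillary <- if (config$simulate) stage("ancillary", {
    centered <- median_center_ratios(sim$tmt)
    enr <- test_enriched_interactors(centered, config$fc_threshold,
                                     config$p_threshold)
    def <- de_filter(sim$de, config$padj_threshold, config$lfc_threshold)
    growth_fit <- fit_malthusian_growth(sim$growth$day, sim$growth$count)
    mdiff <- mirna_differential(
      sim$mirnas[, c("mirna_id", "count")],
      perturb_mirna_counts(sim$mirnas, config$sim))
    list(n_enriched = sum(enr$significant), de_up = def$n_up,
         de_down = def$n_down, growth = growth_fit,
         n_mirna_changed = sum(abs(mdiff$log2fc) > 0.5))
  }) else NULL

  report$summaries <- list(
    n_reads_ago = nrow(sim$reads_ago),
    n_clusters_ago = nrow(clusters$ago),
    n_clusters_fam = nrow(clusters$fam),
    read_distribution = annotated$read_distribution,
    seed_set = list(top_n = seeds$set$top_n,
                    cumulative_fraction = seeds$set$cumulative_fraction),
    rnai_comparisons = rnai$comparisons,
    cobinding = cobind$summary[c("n_sites_a", "n_sites_b", "n_a_overlapped",
                                 "site_overlap_fraction", "nucleotide_jaccard",
                                 "raw_cluster_overlap_fraction")],
    n_cobound_genes = length(cobind$summary$cobound_genes),
    stabilization = cobind$stabilization,
    ancillary = if (is.null(ancillary)) NULL else list(
      n_enriched_interactors = ancillary$n_enriched,
      de_up = ancillary$de_up, de_down = ancillary$de_down,
      growth_doubling_days = ancillary$growth$doubling_time,
      growth_r_squared = ancillary$growth$r_squared,
      n_mirna_changed = ancillary$n_mirna_changed)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, na = "null",
                       pretty = TRUE)
  write_manifest(TRUE)
  invisible(report)
}

# Echo of the scientific settings (paths and output locations excluded so the
# report is byte-identical across runs in different directories).
config_echo <- function(config) {
  list(sim = unclass(config$sim),
       caller = unclass(config$caller),
       top_n_mirnas = config$top_n_mirnas, seed_flank = config$seed_flank,
       bins = config$bins, split_percentile = config$split_percentile,
       min_count = config$min_count, min_samples = config$min_samples,
       padj_threshold = config$padj_threshold,
       lfc_threshold = config$lfc_threshold,
       fc_threshold = config$fc_threshold, p_threshold = config$p_threshold)
}

# A small KO perturbation of the miRNA profile used by the pipeline's
# miRNA-differential demo: 10% of miRNAs shift two-fold either way on top of
# mild biological noise.
perturb_mirna_counts <- function(mirnas, sim) {
  set.seed(derive_seed(sim$genome_seed, 9L))
  n <- nrow(mirnas)
  eff <- rnorm(n, 0, 0.1) +
    ifelse(runif(n) < 0.1, sample(c(-1, 1), n, replace = TRUE), 0)
  data.frame(mirna_id = mirnas$mirna_id,
             count = pmax(0, round(mirnas$count * 2^eff)),
             stringsAsFactors = FALSE)
}
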