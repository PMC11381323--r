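# riscshift

Simulation-backed analysis of RNAi activity and RNA-binding-protein
competition from PAR-CLIP data.

## The problem

Argonaute (AGO) proteins loaded with miRNAs repress their target
transcripts. Whether that repression is actually operating in a given
cellular state is hard to read off any single gene: individual effects are
small, so the field's standard readout is a **cumulative-distribution
comparison** — rank genes by AGO binding-site load from CLIP data, keep only
targets with miRNA seed-match evidence, and test whether the log2
fold-change ECDF of the most-bound targets shifts left of that of expressed
non-targets. A second, competing signal complicates this picture: RNA-binding
proteins such as FAM120A can co-occupy AGO target transcripts and shield
them, so co-bound targets escape repression in proportion to AGO/FAM120A
overlap.

riscshift implements this whole analysis chain as a tested R package —
conversion-aware cluster calling from PAR-CLIP reads, transcript-feature
annotation, 6mer seed filtering against the expressed miRNA pool, occupancy
ranking with ECDF/KS comparisons, co-binding and stabilization analysis, and
the surrounding defined computations (TMT interactome enrichment filter, DE
thresholding, miRNA fold changes, Malthusian growth fits). Because the point
is the statistical machinery, the package also contains a first-class
synthetic-data module that generates every input with planted ground truth,
so each stage's recovery can be verified quantitatively. It is aimed at
computational biologists who want a transparent, fully reproducible desk-scale
implementation of the CLIP-to-repression analysis, with every convention
pinned down and tested.

## The model at the core

The synthetic study plants, per gene $g$,

$$\mathrm{lfc}(g) = -\beta\, w(g)\, \mathrm{seed}(g)\,(1 - \gamma\,\mathrm{cobound}(g)),$$

with occupancy weight $w(g)$ (planted site count scaled to max 1), seed-match
indicator, co-binding indicator and stabilization strength
$\gamma \in [0,1]$; observed log2FCs add Gaussian noise. The analysis side
never sees the truth: it calls binding sites from T-to-C conversion evidence
(normalised conversion-vs-background kernel densities, PARalyzer-style),
ranks seed-matched targets by cluster count, bins percentiles (5, 20] and
(25, 100], and compares each bin with non-targets by a two-sided two-sample
Kolmogorov–Smirnov test plus median shift. Co-bound genes are split at the
top 25% of AGO occupancy; a co-bound bin whose absolute median shift is
smaller than the AGO-only targets' is flagged *stabilized*. The methods
vignette (`vignettes/riscshift-methods.Rmd`) documents every model,
parameter and convention.

## Worked example

```r
library(riscshift)

cfg <- sim_config(n_genes = 400, genome_seed = 7, n_ago_sites = 200,
                  n_fam_sites = 200, n_target_genes = 120)
tx    <- generate_transcriptome(cfg)
truth <- plant_binding_sites(tx$models, tx$genome, cfg)

# call clusters from simulated PAR-CLIP reads and check them against truth
reads    <- simulate_parclip_reads(truth, cfg, "ago")
clusters <- call_clusters(reads, truth$genome)
benchmark_cluster_calls(clusters, truth$ago_sites)[c("precision", "recall")]
#> $precision
#> [1] 1
#> $recall
#> [1] 0.955

# the ECDF analysis on the same planted study
run <- rnai_recovery_run(tx, cfg)
run$comparisons[, c("group_label", "n_group", "ks_D", "p_value", "median_shift")]
#>   group_label n_group      ks_D     p_value median_shift
#> 1  mid_25_100      80 0.2464286 0.001044731   -0.1134064
#> 2    top_5_20      16 0.4107143 0.008185465   -0.1890114

run$stabilization[, c("group_label", "n_group", "median_shift", "p_value", "stabilized")]
#>    group_label n_group median_shift      p_value stabilized
#> 1  cobound_all      79  -0.06343877 1.440585e-01       TRUE
#> 2 cobound_high      20  -0.08882331 3.382385e-01       TRUE
#> 3  cobound_low      59  -0.05093598 2.793082e-01       TRUE
#> 4       a_only      41  -0.22040223 1.099837e-06       NA
```

Reading the output: the cluster caller recovers 95.5% of the 200 planted
sites with no false calls. The top-occupancy bin of seed-matched targets is
shifted −0.19 log2 units below non-targets (KS p ≈ 0.008) and the middle bin
−0.11 — repression scales with binding-site load. Genes co-bound by FAM120A
sit near zero shift while AGO-only targets carry −0.22, so every co-bound
bin is flagged stabilized: the planted competition ($\gamma = 0.8$ here)
is recovered.

## The analysis, stage by stage

The `analysis/` directory holds numbered drivers that run the full study on
disk files under `results/study/` (simulate → call clusters → annotate +
seed filter → RNAi ECDFs → co-binding → ancillary statistics → consolidated
report):

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

Stage 7 also verifies end-to-end determinism: two runs of the same
configuration produce byte-identical `report.json` files.

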