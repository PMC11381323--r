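---
title: "riscshift: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{riscshift: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

riscshift quantifies two intertwined regulatory signals from PAR-CLIP-style
data: **RNAi activity** — the repression of Argonaute (AGO) targets, read off
as a leftward shift in the cumulative distribution of their expression log2
fold changes relative to non-targets — and **RBP competition** — the
attenuation of that repression on transcripts co-bound by a competing
RNA-binding protein (FAM120A). Because the statistical machinery is the
deliverable, every input is synthetic with planted ground truth: the package
generates the study, analyses it blind to the planting, and then checks what
it recovered. This vignette records the models, the parameters that matter,
and the design decisions taken where the design was genuinely open.

## The planted repression model

Each gene's planted ("true") log2 fold change follows

$$\mathrm{lfc}(g) \;=\; -\beta \; w(g)\; \mathrm{seed}(g)\,
  \bigl(1 - \gamma\, \mathrm{cobound}(g)\bigr),$$

where

* $\beta$ (`repression_beta`, default 0.5) is the maximal repression
  magnitude in log2 units — chosen to sit at the conventional
  differential-expression threshold, so planted effects are realistic rather
  than caricatured;
* $w(g) \in (0, 1]$ is the **occupancy weight**: the gene's planted AGO site
  count scaled by the maximum over genes, making repression monotone in
  binding-site load with the most-bound gene at full effect;
* $\mathrm{seed}(g)$ is 1 only if at least one AGO site of the gene carries a
  planted 6mer seed-match motif — targets without seed evidence are never
  repressed, which is exactly the assumption the analysis' seed filter
  encodes;
* $\gamma$ (`stabilization_gamma`) scales protection on co-bound genes: 1
  means full stabilization (the co-bound ECDF collapses onto non-targets), 0
  means FAM120A binding is inert.

Observed log2FCs add $N(0, \sigma^2)$ noise (`lfc_noise_sd`, default 0.2 —
a typical RNA-seq log-fold-change dispersion for moderately expressed genes).
P-values are the two-sided normal tail of the observed effect over $\sigma$,
then Benjamini–Hochberg adjusted; this gives a monotone, realistically-shaped
`padj` column without fitting a count model. Base means are log-normal
(meanlog 5, sdlog 1.5). A consequence worth noting: at these defaults almost
no single gene clears `padj < 0.01` *and* `|log2FC| > 0.5` — the planted
repression is a distribution-level signal, which is precisely why the
analysis works on ECDFs rather than per-gene significance calls.

## What the generator emulates, and what it does not

The simulated study comprises a toy transcriptome (single-isoform genes with
5'UTR / split CDS / intron / 3'UTR, ~25 genes per chromosome, intergenic gaps
≥ 500 nt, 0-based half-open coordinates throughout), planted binding sites,
footprint reads with T-to-C conversion evidence, a heavy-tailed miRNA
profile, and the matched expression, proteomics and growth tables.

Key generative choices:

* **Site placement.** AGO sites follow fixed per-class quotas from
  `feature_bias` (default 70% 3'UTR, 15% CDS, 10% intron, 5% 5'UTR),
  reflecting the 3'UTR-dominant occupancy of AGO CLIP data. Quotas are exact
  by largest-remainder allocation; when a gene is too crowded the site moves
  to another gene, never to another feature class, so the realized
  composition equals the configured one. Sites keep ≥ `site_margin` (100 nt)
  separation so cluster calls are unambiguous.
* **Exact overlap planting.** Exactly
  `round(rho * n_ago_sites)` AGO sites receive an overlapping FAM site,
  displaced by at most half a footprint — both proteins compete for the same
  element, so designated pairs share most of their 24 nt footprints. All
  other FAM sites go to genes without AGO sites; gene-level co-binding and
  site-level overlap therefore coincide in the truth. Co-bound *genes* are
  drawn uniformly among target genes, not in proportion to site count;
  site-proportional sampling would make co-bound genes systematically more
  occupied than AGO-only genes and confound the $\gamma = 0$ comparison.
* **Crosslink chemistry.** Each site's crosslink is the sense-strand
  reference T (plus-strand A on minus-strand genes) nearest the site
  midpoint; T-to-C conversion requires a reference T on the read's sense
  strand. Seed motifs are written into the genome so they never cover the
  crosslink.
* **Reads.** Per-site counts are negative-binomial (`mean` 20, `size` 10);
  footprints are 20–40 nt, centred near the crosslink with ±6 nt jitter. A
  read covering the crosslink converts there with probability
  `conversion_rate` (0.3); every other covered sense T converts with
  probability `error_rate` (1e-3). Five percent of reads are uniform genomic
  background. The footprint length range is a stand-in — fragment-length
  distributions of RNase-trimmed footprints vary by protocol — and is
  exposed in the configuration.
* **miRNA profile.** 500 random 21–22 nt RNA species with Zipf-law counts
  (exponent 1.1), so the top 200 carry ~90% — concentrated, but below the
  95% regime the seed-set construction warns about. The planted site motifs
  come from the top 20 species.

Not emulated: isoform complexity, ncRNA classes, sequencing-quality models,
alignment artefacts, PCR duplication, and any count-level DE model. Passing
tests therefore demonstrate that the *analysis* recovers planted effects
under clean conditions; they say nothing about alignment robustness or
count-model misspecification on real libraries.

## Cluster calling

The caller is a desk-scale conversion-density model in the spirit of
kernel-density CLIP cluster callers. Reads are grouped into maximal
same-strand overlap chains (gap ≤ `merge_gap`, default 0). Within a group,
two **normalised** Gaussian KDEs (bandwidth 3 nt) are compared position by
position: one over conversion events, one over covered, unconverted sense-T
positions. Normalisation matters: at a per-read conversion rate of 0.3 the
raw unconverted-T event mass always exceeds the converted mass, so only the
*density shapes* — conversion evidence concentrated at the crosslink versus
background spread over every covered T — are informative. Cluster candidates
are maximal runs where conversion density ≥ non-conversion density (ties
resolve toward conversion, favouring sensitivity); the **mode location** is
the run's conversion-density argmax (smallest coordinate on ties).

The emitted cluster interval is the region spanned by the run's supporting
reads, i.e. the footprint-scale unit a CLIP cluster represents; the
conversion-dominant run itself is narrower than the protected footprint and
is used only for the conversion statistics.

Filters: `min_reads` 5, `min_conversion_locations` 1, and `min_t2c_fraction`
0.1. The last default is an operating-characteristic choice: error-only
clusters carry a spurious conversion in fewer than 1% of reads
($1-(1-10^{-3})^{7.5} \approx 0.0075$ for ~7.5 covered Ts), an order of
magnitude under the cut, while genuine sites at conversion rate 0.3 fall
below 0.1 with probability under 1% at 20 reads
($P[\mathrm{Binom}(20, 0.3) \le 1] = 0.0076$). A cut at 0.2 would discard
more than a tenth of true sites by binomial noise alone, which is why it is
not the default.

## Feature annotation

A cluster's category is the feature class containing its mode location on
the matching strand — crosslink-centric, single-valued assignment. When
isoforms disagree, the declared priority is 3'UTR > 5'UTR > CDS > intron
(3'UTR first because it is the headline category of AGO occupancy), with
lexicographic transcript id as the final tiebreak, making the result
independent of annotation order. Reads are attributed to clusters by
midpoint containment (no double counting); reads outside every cluster count
as `other`, and fractions always sum to 1.

## The seed filter

The 6mer seed is miRNA positions 2–7 (the canonical definition; "6mer"
alone does not pin the register) and a target site is its reverse complement
in the bound RNA. Matching is exact, case-insensitive, with overlapping
occurrences counted and `N` never matching. The expressed seed set is the
top 200 miRNAs by RPM (ties to the lexicographically smaller id), with the
cumulative expression fraction reported and a warning when it reaches 95%.
Seeds are searched in the cluster sequence ±10 nt flank rather than the
whole transcript: the filter should tie target status to the observed
binding evidence, not to a match anywhere in a long 3'UTR. A whole-region
scan is available by passing transcript intervals to the same scanner.

## Ranking, binning and the ECDF comparison

Occupancy is the number of binding-site clusters per gene (the
read-count-weighted alternative sits behind `weight_by_reads`). Percentiles
are computed *after* the seed filter, over seed-matched bound expressed
genes, descending (percentile 1 = most bound); ties rank the smaller gene id
worse, stably. The default bins are percentiles (5, 20] and (25, 100] —
reproducing the ranking convention literally, including the gaps (0, 5] and
(20, 25], which stay unbinned; both bins are configurable. Non-targets are
expressed genes with zero clusters; genes bound without seed evidence are
*excluded*, not treated as non-targets — a conservative reference, since
seedless binding may still repress weakly.

The two-sided two-sample Kolmogorov–Smirnov test is the declared choice for
distribution comparison (the convention behind ECDF significance stars
rarely names its test; KS is assumption-light and matches the sup-distance
geometry of an ECDF plot). The D statistic is computed directly from the
pooled order; p-values use the exact tie-aware two-sample distribution
(`stats::psmirnov`) when the smaller sample is under 30, and the asymptotic
Kolmogorov series otherwise. The accompanying effect size is the median
shift (group median minus reference median) in log2 units.

## Co-binding and stabilization

Site overlap is reported site-level (fraction of AGO sites touched by ≥ 1 nt
of a same-strand FAM site — the natural reading of a site-overlap
percentage) alongside a nucleotide-level Jaccard, to avoid committing to one
convention. When estimating overlap from *called* clusters, footprint-scale
intervals (24 nt, centred on each cluster's mode) are reconstructed first:
the conversion run marks the crosslink, not the footprint, and intersecting
raw runs would understate overlap.

For stabilization, co-bound genes are split at the top 25% of AGO occupancy
("binding preference" = cluster count; read-count and conversion-signal
alternatives were considered and left behind the same flag as occupancy
weighting) versus the rest, and each bin — plus all co-bound genes pooled
and the AGO-only targets — is compared with non-targets (genes bound only by
FAM120A are removed from the reference). A co-bound bin is **stabilized**
when its absolute median shift is smaller than the AGO-only targets':
co-binding buys back repression. With $\gamma = 1$ the co-bound bins sit at
zero shift while AGO-only targets carry $-\beta$-scaled repression; with
$\gamma = 0$ the two coincide — both recoveries are asserted in the test
suite at ±0.1 in log2 units.

## Ancillary computations

* **TMT enrichment filter.** KO/WT log2 ratios are median-centred per block
  (exactly zero median, idempotent); per-protein equal-variance Student's
  t-test (Welch behind `var_equal = FALSE`; "Student's" is read as pooled
  variance). Significance = mean log2 ratio ≥ log2(1.5) (inclusive) **and**
  p < 0.075 (strict), one-directional because the question is *enhanced*
  interaction. Zero-variance proteins get an undefined p, a `degenerate`
  flag, and are never significant.
* **DE filter.** `padj < 0.01` and `|log2FC| > 0.5`, both strict as
  conventionally printed; up/down sets plus pairwise overlaps.
* **miRNA differential.** RPM per condition with pseudocount 1 on the
  numerator (zero-count robustness), `log2(KO/WT)`, ranked.
* **Growth.** Least squares on `ln(count)` vs time; doubling time
  `ln 2 / k`, undefined (flagged) when `k ≤ 0`. Noiseless exponential input
  is recovered to machine precision.

## Determinism and problem sizes

All randomness routes through one master seed; each generator stage derives
its own stream, so identical configurations give byte-identical serialized
outputs — the orchestrated pipeline writes reports that hash identically
across runs. The test suite and the acceptance script exercise the recovery
properties at desk scale, chosen for statistical adequacy: type-I
calibration uses 200 replicates of a 1000-gene / 200-target study (binomial
SE of the rejection rate ≈ 0.015 against a ±0.03 band); repression recovery
50 replicates; stabilization 25 per $\gamma$ extreme on a 700-gene study
with ~195 co-bound genes; the caller benchmark 200 planted sites; the
read-category recovery 500 sites, where the read-weighted binomial SE
(~0.022) sits comfortably inside the ±0.05 check (at 200 sites it would not).

## Known limitations

The caller models conversion density only — no read-profile KDE, no
multi-sample joint calling — and inherits the usual KDE edge behaviour on
very sparse groups. The expression model plants effects directly on log2FCs,
so count-level phenomena (dispersion–mean coupling, independent filtering)
are out of reach. Gene-level co-binding is all-or-nothing: one overlapped
site stabilizes the whole gene under $\gamma$, with no per-site dosage. The
miRNA KO perturbation used by the differential demo is a simple spike model.
These are deliberate simplifications that keep every planted quantity
recoverable in closed form.
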