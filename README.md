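# pausekit

Quantifying RNA polymerase II promoter-proximal pausing, single-cell
gene–gene covariance shifts, and signature-based survival stratification —
the three computational tracks needed to study how an oncogenic
transcription factor (the motivating case is MYC in prostate luminal
cells) can dismantle a hormone-receptor transcriptional program, here the
androgen receptor (AR) program, without changing receptor levels. The
package is aimed at computational biologists working with Pol II ChIP-seq
coverage, 10x-style UMI count matrices, and expression + survival cohort
tables.

## What it computes

**Traveling ratio (pausing index).** For each gene, with the promoter
window −30 bp…+300 bp around the TSS (strand-aware) and the gene body the
remaining gene length,

    TR = d(promoter) / d(body),   d(R) = (Σ coverage / |R|) · 1e6 / N

with densities in mean per-base coverage per million mapped fragments
(per-bp BPM, library size N). TR ≫ 1 means promoter-proximal pausing. The
per-gene difference Δ = TR₁ − TR₂ between conditions is ranked ascending
and rescaled to the unit square; the points where a line of slope 1 is
tangent to that curve mark where Δ "takes off" in each tail, and genes
beyond them are classified as **pause-release** (upper tail, TR lost in
condition 2) and **pause** (lower tail, TR gained). Gene-set TR
distributions are compared between conditions with the two-sample
Kolmogorov–Smirnov test (exact for small sets) or Welch's t test.

**Anchor covariance shift.** Per gene, the sample covariance with an
anchor gene (e.g. *Ar*) across cells of each condition on
total-count-normalized, un-logged expression; genes with
|cov₁ − cov₂| > 30 are flagged. Includes the standard UMI QC (< 200
detected genes or > 80% mitochondrial UMIs excluded), a per-population
transgene-positive census, and pseudobulk/bulk log-scale Pearson
concordance.

**Stratification.** Rank-based signature scores in [0, 1] (mean signature
rank rescaled between its attainable extremes — monotone-transform
invariant), cutpoints by maximally selected standardized log-rank
statistics over the 10–90% score quantiles, AR×MYC quadrant groups
(strictly-above = high), and Kaplan–Meier / k-group log-rank via the
survival package. The nine-gene AR-A signature (KLK3, KLK2, FKBP5,
STEAP1, STEAP2, PPAP2A, RAB3B, ACSL3, NKX3-1) is built in.

Each track has a seeded synthetic-data generator with planted ground truth
(pausing shifts, covariance structure, hazard quadrants), so the whole
pipeline is testable end to end without any external data.

## Worked example

Simulate a two-condition Pol II experiment with 15 planted pause-release
genes (pause fraction 0.55 → 0.15) and 25 planted pause genes (0.55 →
0.85) among 400 genes, then recover them:

```r
library(pausekit)
cfg <- polii_sim_config(
  n_genes = 400, reads_per_gene_mean = 300,
  planted_pause_release = setNames(rep(-0.4, 15), sprintf("g%05d", 1:15)),
  planted_pause = setNames(rep(0.3, 25), sprintf("g%05d", 16:40)),
  seed = 7)
genes <- simulate_gene_models(cfg)
sim <- simulate_polii_experiment(genes, cfg)
tr1 <- compute_tr_table(sim$track1, genes)
tr2 <- compute_tr_table(sim$track2, genes)
head(tr1[, c("gene_id", "promoter_density", "body_density", "tr")], 3)
#>   gene_id promoter_density body_density    tr
#> 1  g00001            678.2        78.94 8.591
#> 2  g00002            579.6        60.72 9.546
#> 3  g00003            624.7        68.23 9.156

curve <- tr_difference_curve(tr1, tr2)
classes <- classify_pause_genes(curve, tangent_cutpoints(curve))
classes
#> <pause_classes> 18 pause-release, 30 pause gene(s)
```

The promoter of gene `g00001` is ~8.6-fold denser than its body (baseline
pausing); the classifier recovers the planted sets with Jaccard 0.83 for
both classes at this demo size. A transgene census on a labeled matrix
with 17/93, 3/35 and 1/8 positive cells prints the expected percentages:

```r
mat <- cell_matrix(
  counts, genes = c(sprintf("g%03d", 1:100), "tg"),
  cells = sprintf("c%04d", 1:136),
  cell_labels = rep(c("basal", "hematopoietic", "vascular_endothelium"),
                    c(93, 35, 8)))
transgene_census(mat, "tg")
#>             population n_cells n_positive percent_positive
#> 1                basal      93         17             18.3
#> 2        hematopoietic      35          3              8.6
#> 3 vascular_endothelium       8          1             12.5
```

`run_pipeline(list(track = "demo", out_dir = "demo_out", seed = 7))` runs
all three tracks on synthetic data and writes TR tables, the ranked
curve, pause classes, covariance-shift and census tables, scores,
cutpoints, quadrant groups, KM curves and a `manifest.tsv` of output MD5
hashes (identical config + seed ⇒ identical hashes). A thin shell entry
point with the same subcommands ships in `inst/scripts/pausekit`.

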