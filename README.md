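# methylmark

Targeted DNA-methylation analysis of cell-type composition from a handful
of CpG sites.

Tissues are mixtures of cell types, and bulk DNA-methylation measurements
average over that mixture. Because many CpG sites carry stable,
cell-type-specific methylation, a small number of well-chosen sites is
enough to (i) classify a sample's dominant cell type, (ii) score the
relative fibroblast/MSC content of a tissue, and (iii) estimate full
cell-type proportions — cheaply enough for targeted assays such as
pyrosequencing, where measuring thousands of CpGs is not an option.
`methylmark` is for epigenomics researchers who want to select such
markers from labelled reference β-value matrices (BeadChip or
pyrosequencing) and apply them to new samples.

## What it computes

**Marker selection.** For a target cell type \(C_i\) versus all others
\(C_{other}\), each CpG gets, per fold of a stratified k-fold
cross-validation:

- `dMean` = mean β in \(C_i\) − mean β in \(C_{other}\) (sign gives
  hyper-/hypomethylated direction),
- `sVar` = within-group variance of \(C_i\) + within-group variance of
  \(C_{other}\).

Candidates are gated by an adaptive parabola in the (dMean, sVar) plane,
`sVar < (a·dMean)²`, with `a` starting at 0.1 and widening in steps of 0.1
until at least 10 hyper- and 10 hypomethylated CpGs pass. Each gated CpG
is scored on the held-out samples by the area under the precision-recall
curve (AUPR), scaled by |dMean|; the final score is the mean scaled AUPR
over the folds where the CpG passed, multiplied by the fraction of folds
where it was selected. A best-F1 variant (unscaled) is available.

**FibroScore.** A two-CpG score for fibroblast/MSC content:
`β(cg18096962) − β(cg18005280)` (hypermethylated minus hypomethylated
fibroblast marker), in [−1, 1]; samples with score ≥ 0 classify as
fibroblast/MSC. Group comparisons use a two-sided Welch t-test.

**Deconvolution.** A reference matrix `R` (marker CpGs × cell types) of
mean training β values is fit to each sample `b` by non-negative least
squares, `min ‖Rw − b‖₂, w ≥ 0`, and the weights are normalized to
proportions `w/Σw`. Samples missing a marker CpG are excluded (flagged,
with the reason) rather than estimated from a partial signature.

**Synthetic data.** A seeded generator produces pure cell-type profiles
(Beta-distributed β values, each type hypomethylated at its own markers),
planted-marker selection benchmarks, and in-silico DNA mixtures with
ground-truth proportions, so the whole pipeline is testable without any
external download.

## Worked example

```r
library(methylmark)

# simulated benchmark: 5 cell types, 10 samples each, 10 planted
# hypomethylated markers per type among 450 background CpGs
cfg <- sim_config(seed = 42)
sim <- simulate_selection_benchmark(cfg)

labels <- setNames(sim$annotation$cell_type, sim$annotation$sample_id)
plan <- stratified_folds(labels, k = 5, seed = 42)
rk <- rank_markers(sim$matrix, sim$annotation, target = "fibroblast", plan)
head(as.data.frame(rk[rk$direction == "hypo", ]), 3)
#>        cpg_id direction selection_frequency mean_metric mean_dMean final_score rank
#> 255 cgM000003      hypo                   1       0.783     -0.783       0.783    1
#> 256 cgM000006      hypo                   1       0.770     -0.770       0.770    2
#> 257 cgM000007      hypo                   1       0.762     -0.762       0.762    3
```

The top hypomethylated candidates are planted fibroblast markers
(`cgM000001`–`cgM000010`), selected in every fold (`selection_frequency`
1) with near-perfect held-out AUPR scaled by the ~0.78 group separation.

```r
# reference-based deconvolution of 50 in-silico DNA mixtures
markers <- sim$truth$cpg_id[sim$truth$role == "marker"]
ref <- build_reference(sim$matrix, sim$annotation, markers)
mix <- simulate_mixtures(unclass(ref), n_mixtures = 50, cfg = cfg)
est <- deconvolve(mix$matrix, ref)
head(as.data.frame(est)[, 1:6], 3)
#>   sample_id endothelial epithelial fibroblast hepatocyte leukocyte
#> 1    mix001        0.08       0.17      0.182      0.559     0.012
#> 2    mix002        0.13       0.15      0.066      0.474     0.172
#> 3    mix003        0.21       0.38      0.202      0.076     0.137

ev <- evaluate_mixtures(mix$truth, est)
max(ev$mae_per_type); ev$rmse; ev$pearson_r
#> max per-type MAE = 0.0066, RMSE = 0.0076, r = 0.9991
```

Estimated proportions sum to 1 per sample and recover the ground-truth
mixing weights to well under one percentage point at the generator's
default measurement noise (SD 0.02).

```r
# FibroScore on three samples measured at the two marker CpGs
v <- rbind(cg18096962 = c(0.88, 0.12, 0.85),
           cg18005280 = c(0.07, 0.81, 0.12))
colnames(v) <- c("fib_line", "huvec", "msc")
fs <- fibro_score(beta_matrix(v))
fs$predicted <- classify_fibro(fs)
fs
#>   sample_id score missing  predicted
#> 1  fib_line  0.81   FALSE fibroblast
#> 2     huvec -0.69   FALSE      other
#> 3       msc  0.73   FALSE fibroblast
```

A command-line wrapper with subcommands `select`, `fibroscore`,
`deconvolve` and `simulate` ships at `inst/cli/methylmark`
(`methylmark_cli()` in R).

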