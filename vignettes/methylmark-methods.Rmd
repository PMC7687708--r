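---
title: "Marker selection, FibroScore and NNLS deconvolution: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker selection, FibroScore and NNLS deconvolution: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylmark)
```

`methylmark` covers three connected tasks in targeted DNA-methylation
analysis: selecting individual cell-type-specific CpG markers from
labelled β-value matrices, scoring fibroblast/MSC content with two CpGs,
and estimating cell-type proportions from a minimal CpG signature by
non-negative least squares. This vignette explains the statistical model
behind each step, the tunable parameters, the numerical conventions, and
the design decisions that were genuinely open — together with what the
synthetic-data generator does and does not establish about real data.

## Data model

A β value is the methylation fraction at a CpG site, in [0, 1]. The
package's central container is a numeric matrix with CpG ids as rows and
sample ids as columns; an attribute records whether the input arrived as
pyrosequencing-style percentages and was divided by 100. Under
`scale = "auto"` rescaling triggers when any value exceeds 1.5 — not 1.0,
so that minor above-1 artifacts in genuine β matrices (which are clipped,
within a 1e-9 tolerance) never cause a silent division by 100.

Platform-level probe filtering — restricting to CpGs shared between array
generations, dropping sex-chromosome probes — is expressed as plain-text
keep/drop lists rather than parsed from array manifests. This keeps the
filter semantics without a dependency on manifest versions, which also
means CpG universes obtained elsewhere with specific manifests are not
reproduced here. A `drop_missing` switch removes CpGs not measured in
every sample.

## Marker selection

For a target cell type against the pooled rest, each CpG is summarized by
`dMean`, the difference of group means (target minus rest, in [-1, 1]; the
sign distinguishes hyper- from hypomethylated candidates), and `sVar`, the
sum of the two unbiased within-group variances (denominator n−1; the
conventional estimator — configurable code would add little, so it is
fixed and documented).

Selection runs inside a stratified k-fold cross-validation (default
k = 10, seeded, fold sizes per class differing by at most one). For each
fold:

1. `dMean` and `sVar` are computed on that fold's samples.
2. CpGs passing the parabola gate `sVar < (a·dMean)²` are selected. `a`
   starts at 0.1 and is widened by 0.1 until at least `min_hyper` (10)
   hypermethylated and `min_hypo` (10) hypomethylated CpGs pass. A cap
   `a_max = 10` prevents infinite escalation on pathological inputs; when
   hit, the CpGs passing at the cap are returned with a warning rather
   than an error.
3. Every selected CpG is scored on all samples *outside* the fold by the
   area under the precision-recall curve (average-precision formulation,
   ties sharing a threshold) or, for the two-CpG fibroblast score variant,
   by the best F1 over all thresholds. Scores are oriented by direction —
   hypomethylated markers use 1 − β — so that higher always means more
   target-like; by monotone invariance of both metrics this is equivalent
   to using −β.
4. The metric is scaled by |dMean| of that fold (disabled for the F1
   variant).

The final score of a CpG is its mean scaled metric over the folds in
which it passed the gate, multiplied by the fraction of folds where it
passed. Averaging over only the selected folds is deliberate: the metric
is never computed in folds where the CpG was not selected, and rarity is
already penalized by the frequency factor. CpGs never selected score 0.
Hyper- and hypomethylated candidates are ranked separately; ties break by
larger |mean dMean|, then lexicographic CpG id, making runs
bit-reproducible. Fold assignment is the only stochastic component and is
driven by one integer seed.

Two readings of "per fold" were possible: compute statistics and
selection on the fold's own samples and evaluate on the remaining folds,
or select on k−1 folds and evaluate on the held-out one. The package
implements the first. A practical consequence: the within-fold variance
needs at least two samples of each group per fold, so k must not exceed
half the size of the smallest class; `rank_markers` errors with that
advice otherwise. This is why the packaged selection benchmark (five
types, ten samples each) is run at k = 5 rather than the k = 10 default
that suits the several-hundred-sample reference collections the defaults
are aimed at.

## FibroScore

The FibroScore is `β(cg18096962) − β(cg18005280)` — a fibroblast/MSC
hypermethylated CpG minus a hypomethylated one — in [−1, 1]. Samples
lacking either CpG are flagged missing, never silently dropped; only when
neither CpG exists in the matrix is the input rejected.

The classification cutoff is a genuinely open choice: no canonical value
exists beyond the geometry of the score. The default is 0 — the symmetric
point where the hypermethylated marker overtakes the hypomethylated one —
with the boundary tie classified as fibroblast. `best_threshold()`
derives an accuracy-maximizing cutoff from a labelled training set when a
data-driven choice is preferred. Group comparisons use the Welch
(unequal-variance) two-sided t-test, with a pooled-variance option; when
both groups are essentially constant the degenerate limit is returned
directly (p = 0 for different means, p = 1 for equal) instead of a solver
error.

## Deconvolution

The reference matrix holds the mean training β value of each marker CpG
in each cell type. Each sample's marker profile `b` is fit by
non-negative least squares (Lawson–Hanson active set, via
`pracma::lsqnonneg`), and the weights are normalized post hoc to
proportions `w/Σw`. A solver constrained to the simplex would be the
alternative; post-hoc normalization was chosen because the unconstrained
total also carries information (e.g. DNA quality), and the raw weights
are kept alongside the proportions for transparency.

Three QC rules matter in practice:

- **Missing markers.** Under the default `missing_policy = "exclude"` a
  sample lacking any marker CpG is flagged excluded with the reason; a
  signature of eight CpGs is small enough that fitting on seven silently
  would change the estimand. `"drop_rows"` removes the missing rows from
  both sides for exploratory use, refusing when fewer rows than cell
  types would remain.
- **Degenerate solutions.** An all-zero weight vector yields flagged
  `NA` proportions, not a fabricated uniform composition.
- **Conditioning.** The reference's condition number is computed at build
  time and a warning is emitted above 1e6: near-collinear cell-type
  profiles (closely related lineages) destabilize the fit, and the user
  should know before trusting the proportions.

For noiseless convex combinations of a full-column-rank reference, NNLS
recovers the exact proportions; the test suite checks this to 1e-8 and
checks the solver against a dense simplex grid search (step 0.01 per
weight, each grid direction scaled by its optimal non-negative factor) to
within 1e-6 on random 6×4 problems.

## Synthetic data

The generator emulates the statistical structure that targeted
methylation signatures assume:

- **Pure profiles.** Each cell type is hypomethylated at its own marker
  CpGs (mean 0.10) and hypermethylated at other types' markers (mean
  0.85); background CpGs share one per-CpG mean, drawn uniformly from
  [0.2, 0.8], across all types. Biological variation uses a Beta
  distribution reparameterized by (mean, SD), which keeps draws in [0, 1]
  by construction; infeasible parameterizations (SD² ≥ mean·(1−mean)) are
  refused with the bound stated. The default within-type SD of 0.05
  matches the tight within-cell-type spread seen at good marker CpGs in
  reference BeadChip collections.
- **Mixtures.** In-silico DNA mixes are convex combinations of the pure
  per-type means with additive Gaussian measurement noise (default SD
  0.02, reflecting targeted-assay precision), truncated to [0, 1] by
  clipping (the clip count is recorded; at the default SD the induced
  bias is negligible). Proportions come from a symmetric Dirichlet
  (α = 1, uniform on the simplex) or can be supplied explicitly, e.g. an
  incremental two-type gradient.
- **Selection benchmark.** Identical to pure profiles, with the defining
  property that background CpGs are identically distributed across types,
  so the planted markers are the only true signal. The default scale —
  5 types × 10 samples × 10 markers/type plus a few hundred background
  CpGs — keeps a full multi-seed benchmark inside seconds while leaving
  the background large enough for false positives to be possible.

What passing tests on these simulations shows: the selection statistics,
gate, ranking, and NNLS recovery behave correctly under the generative
assumptions (independent Beta noise, exactly block-structured markers,
linear mixing). What they do not show: robustness to batch and study
effects, probe-level artifacts, correlated CpGs, cell types absent from
the reference, or epigenetic aberrations (e.g. in tumors) — all of which
real BeadChip compendia contain and which require real labelled data to
assess.

## Numerical conventions

- TSV output uses 15 significant digits; write/load round trips reproduce
  values to better than 1e-12, and seeded pipeline runs are byte-identical.
- Proportions of non-excluded samples sum to 1 within 1e-9.
- The NNLS contract is checked behaviorally (residual optimality against
  the grid oracle at 1e-6, exactness at 1e-8 on noiseless problems)
  rather than by inspecting solver internals.
- AUPR/F1 threshold handling: tied scores share a threshold; the F1 sweep
  places the classifier at every distinct score value (score ≥ t →
  target), which covers all achievable confusion matrices.
- Empty filter results, empty sample intersections, single-class metric
  calls, and under-sized fold groups are errors with instructive
  messages; the parabola cap is a warning because partial output remains
  meaningful there.

## Known limitations

- Marker selection treats CpGs independently; it will happily rank
  several mutually redundant markers from one differentially methylated
  region.
- The deconvolution estimand is "proportion of DNA from each reference
  type": types missing from the reference are redistributed over the
  included ones, and the FibroScore is a relative, not absolute, measure
  of fibroblast content.
- List-driven probe filtering reproduces filter semantics but not any
  specific published CpG universe, which depends on manifest versions.
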