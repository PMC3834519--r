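---
title: "Methods: multi-omics relapse-signature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics relapse-signature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

`relapsig` operationalizes a feature-selection workflow for a two-group
cohort design common in translational oncology: a modest number of
patients (the reference design is 20 relapse vs 20 relapse-free, sampled
at surgery with long follow-up) profiled on several heterogeneous omics
platforms — tumor gene expression, miRNA expression, DNA copy number,
exome variants, and LC-MS metabolite intensities from serum and urine in
both ESI polarities. The goal is a *minimal* panel of features per data
type that classifies relapse outcome well, followed by an integrative
ranking across data types. At n = 40 the dominant statistical risk is
overfitting, so every stage is built around resampling.

# Pipeline stages

## Significance prefilter

Each feature is tested with the two-sided unequal-variance (Welch) t-test
between the groups; features with raw p at or below a threshold (default
`alpha_prefilter = 0.05`, per-type overrides possible, 0.01 being the
common stricter choice) proceed. No multiplicity correction is applied by
default — the prefilter is a screening device ahead of wrapper selection,
not an inference step; a Benjamini–Hochberg flag (`adjust_bh`) is
available for users who want rigor over fidelity to the screening
workflow. Features with fewer than two observed values in either group
are flagged untestable and excluded rather than passed silently. Two
degenerate conventions are fixed: zero variance in both groups with equal
means gives t = 0, p = 1; with unequal means, p = 0.

## SVM-RFE with Monte-Carlo cross-validation

Recursive feature elimination wraps a soft-margin linear SVM (cost
`svm_cost = 1`, a conventional default since the method is insensitive to
C on standardized inputs; only the linear kernel is supported because the
ranking criterion is the primal weight). At each round the SVM is trained
on all samples and the feature with the smallest squared weight is
removed (ties break toward the lexicographically smaller id so runs are
reproducible); the surviving-set classification accuracy is estimated by
Monte-Carlo 2-fold cross-validation: `mc_reps` (default 200) stratified
random halvings, training on each half and testing on the other, so each
repetition contributes two accuracies and every sample is used for both
training and validation. Standardization always uses training-fold
statistics only. The selected panel is the smallest size attaining the
maximum of the mean accuracy curve, i.e. the minimal panel with maximal
cross-validated accuracy.

### A note on plateaus and panel recovery

When the planted (or true) signal is strong, the mean CV accuracy curve
saturates at 1.0 over a wide range of panel sizes. With a few hundred CV
repetitions, ties at exactly 1.0 extend to panels much smaller than the
number of truly informative features, and the minimal-size rule then
selects a small all-signal panel rather than the full informative set:
once a handful of strong features separate the realized cohort perfectly,
the remaining informative features are *redundant for classification*
even when they are statistically independent, and RFE eliminates them
mid-field. This is an inherent property of margin-based wrapper selection,
not a defect of the implementation; the package's parameter-recovery
tests document it. Users who want full-signal panels should inspect the
whole accuracy curve and the elimination order rather than relying on the
minimal panel alone, or raise `mc_reps` substantially so that tiny
accuracy differences between panel sizes become resolvable.

## Leave-one-out validation and ROC

The selected panel is validated by leave-one-out: each sample is scored
by an SVM trained on the other n − 1. The held-out decision values feed
the ROC analysis: the AUC is the trapezoidal area (equivalently the
Mann–Whitney statistic with half credit for tied scores), and the
confidence interval (default level 0.95) is the percentile interval of
`boot_reps = 2000` stratified bootstrap resamples — resampling within
each outcome group preserves the 20/20 design and guarantees both classes
in every resample. The percentile flavor was chosen over DeLong for
symmetry with the resampling used everywhere else; at the AUC boundary
(perfect separation) the interval collapses against 1, which is the
expected behavior of a percentile interval.

## Chromosomal instability (CIN) index

Copy-number segment profiles (log2 tumor/normal ratios, assumed
normalized upstream against adjacent non-tumor tissue) are summarised per
cytoband and per chromosome. For a region of length L, the gain index
sums `ratio × overlap / L` over segments with ratio at or above `t_gain`
(default +0.2 log2, roughly a single-copy gain at 50% purity); the loss
index sums `|ratio| × overlap / L` over segments at or below −`t_loss`;
the total index is their sum. This amplitude-weighted, length-normalized
definition is *the package's definition*: the literature contains several
CIN variants (including binary altered-fraction versions), and the exact
historical formula behind the workflow we emulate is not published in a
reproducible form. The definition here is continuous in the segment
amplitudes, additive under segment splitting, and exactly equal to a
per-base accumulation — properties the test suite verifies against a
brute-force oracle. The chromosome-level index is the band-length-weighted
mean of band indices when bands tile the chromosome. The resulting
band-by-sample matrix (channel `total`, `gain` or `loss`) enters the same
prefilter → SVM-RFE → LOO path as expression data. A deliberately naive
fixed-window fallback segmenter is provided for probe-level input only;
it is not a change-point method and proper upstream segmentation should
be preferred.

## Variant filtering and burden testing

The annotated multi-sample VCF contract requires INFO keys `GENE`, `CSQ`,
`DEL` (0/1 deleteriousness) and optional `AF`. Two order-independent row
filters produce the candidate set: protein-altering consequence classes
(missense, stop gained/lost, frameshift, splice donor/acceptor, inframe
indels) with `DEL = 1`, and relapse-exclusivity (at least one carrier
among relapse samples, none among relapse-free; missing genotypes count
as non-carriers). The gene-level burden test collapses rare qualifying
variants (annotated population AF below `af_cutoff = 0.05`, falling back
to the cohort allele frequency when unannotated) into per-sample carrier
indicators and applies the two-sided Fisher exact test to the
carrier-by-group table. Pathway-level aggregation over user-supplied GMT
gene sets reports, per set: genes hit, qualifying variants, and carrier
counts among relapse (`n_cases`) and relapse-free (`n_controls`) samples
— after relapse-exclusive filtering the control column is structurally
zero — with a one-sided Fisher enrichment p of variant-bearing genes
against the annotated background.

## Integration: random forests against artificial contrasts

The per-type panels are row-bound into one combined matrix (features
namespaced by type, each row z-scored). Ranking heterogeneous features
jointly uses a random-forest scheme with artificial contrasts: in each of
`rface_forests = 20` repetitions, every feature gets one independently
permuted copy (same values, association destroyed); a forest of
`rface_trees = 100` trees (mtry = ceiling of the square root of the
augmented width, out-of-bag permutation importance) is grown on the
augmented matrix; each real feature's importance is then compared, across
repetitions, with the `rface_quantile = 0.75` quantile of that
repetition's contrast importances via a one-sided paired t-test. The
normalized score is mean importance over mean contrast quantile. This
contrast-testing scheme is this package's concrete definition of
"importance testing against an empirical null"; the historical tool it
emulates was never published in an archival, reproducible form, so the
scheme here is a faithful re-design, documented rather than recovered.
The 0.75 quantile makes the null bar stricter than the median without
being dominated by the single most extreme contrast.

Two thresholds tier the ranking: `p_select = 0.01` defines the selected
set, and `p_top = 1e-30` the top tier. The extreme default for `p_top`
mirrors the workflow being emulated; a paired t-test across 20
repetitions cannot reach such values on desk-scale data (its p-values are
bounded well above that by the t distribution with 19 degrees of
freedom), so on realistic runs the top tier is empty unless `p_top` is
reconfigured (1e-6 is a practical choice). This is intentional: the
default preserves the published threshold, the documentation states its
consequence.

Associations among selected features use Kendall tau-b (tie-corrected),
with p-values from the tie-corrected normal approximation for n ≥ 10 and
exhaustive permutation enumeration below that; edges are kept at
`alpha_edge = 0.01`. Genomic coordinates are attached where they exist
(genes/miRNAs via a user annotation, cytobands via the band map);
metabolite features are unmapped by design.

# The synthetic cohort generator

Because the reference cohort is not publicly deposited, the generator is
a first-class module that emulates the *design*, not the data: 20 + 20
samples; per data type a features-by-samples matrix on log2 scale with
per-feature SD 1, where informative features get a mean shift of
`effect_size` (z units) in the relapse group — so effect sizes are
directly interpretable and the two-sample t-test power is analytically
checkable; copy-number profiles with a neutral background (segment noise
SD 0.05 log2) plus one covering segment per altered cytoband (default 16
bands, amplitude ±0.6, penetrance 0.8 among relapse samples); and
variants whose signal genes carry rare deleterious alleles only in
relapse samples (carrier rate 0.4) on top of a mixed background present
in both groups.

Default per-type informative counts follow the reference panels (12
genes, 25 miRNAs, 16 cytobands, 15/9 serum and 16/18 urine features);
total feature counts (2000 genes, 800 miRNAs, 600 m/z features per
biofluid/mode, 320 synthetic cytobands over 8 chromosomes) are desk-scale
choices — large enough that prefilter false positives outnumber true
signal, small enough that the full pipeline runs in minutes on one core;
they are the package's own choices, stated here once.

Redundancy is modelled with latent-factor blocks, x = sqrt(r)·f +
sqrt(1−r)·e, giving exact within-block correlation r (`block_corr`,
default 0.6, blocks of `block_size = 4`). The blocks are planted on a ~5%
tranche of *background* features, not on the informative ones: correlated
features with no group shift remain exchangeable between groups (so null
calibration holds marginally), while redundancy among the informative
features themselves would make any panel-recovery assessment ill-posed —
a minimal-accuracy panel provably excludes redundant signal (see the
plateau note above).

What the generator does **not** emulate: raw reads or spectra,
probe-level intensities, batch and platform effects, heavy-tailed or
skewed intensity distributions, missingness mechanisms, correlation
*between* data types, purity/ploidy structure in copy number, and linkage
between variants. Passing tests on this cohort therefore demonstrate
algorithmic correctness and statistical calibration under a clean
Gaussian design — not robustness to the full messiness of real multi-omic
data.

# Numerical and I/O conventions

* All genomic intervals are 0-based half-open internally; SEG files are
  read as 1-based inclusive and converted; BED is native 0-based.
* Matrices round-trip through TSV at 6 significant digits.
* Missing matrix cells are allowed on input; features with more than 20%
  missing are dropped with a warning, the rest are mean-imputed per
  feature before modeling (the emulated workflow is silent on
  missingness; this is the package's documented choice).
* Raw LC-MS matrices can be passed through a sequential normalization
  chain — per-sample total-intensity scaling to the cohort median total,
  log2(x + 1), per-feature z-score — applied explicitly (or by the
  pipeline when `normalize_metabolomics = TRUE`) and recorded in the
  run metadata. The chain is a documented stand-in for an
  under-specified "row-wise/column-wise sequential" normalization.
* Every stochastic stage derives its own sub-seed deterministically from
  the config seed, so a full `run_pipeline()` is byte-identical across
  repeats with the same seed (wall-clock timings go to the log only).
* SVM decision values are oriented by placing positive-class samples
  first at fit time (the underlying solver orients its decision function
  by the first class encountered), making score signs stable under
  sample permutation.

# Test-suite problem sizes

The suite exercises the full pipeline at reduced sizes chosen once:
oracle comparisons use 500–1000 random small instances per statistic
(Welch vs `stats::t.test`, Fisher vs exhaustive table enumeration, tau-b
vs brute-force pair counting, AUC vs concordant-pair counting, CIN vs
per-base accumulation); parameter recovery runs the full 2000-gene,
12-signal design at `mc_reps = 200` over seeds 1–5; type-I checks use 10
pure-noise cohorts of 200 features; bootstrap coverage uses 100 null
cohorts; end-to-end determinism uses a compact all-component cohort.

# Known limitations

* The CIN definition and the contrast-testing scheme are documented
  re-designs of methods whose original formulations are not publicly
  reproducible; results should be compared across tools with that in
  mind.
* The minimal-panel rule is unstable on accuracy plateaus (see above).
* Fisher burden testing ignores variant count per sample (carrier
  collapse only); CMC/SKAT-style weighting is out of scope.
* No segmentation method beyond the naive fallback; no purity/ploidy
  correction; no tumor/normal subtraction (somatic status is trusted
  from the input VCF).
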