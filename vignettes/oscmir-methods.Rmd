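---
title: "Models and methods behind oscmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind oscmir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscmir)
```

`oscmir` analyzes two-class (tumor vs normal epithelium) miRNA expression
matrices from small-RNA sequencing (read counts) or RT-qPCR (Ct values).
This vignette is the package's account of its statistical choices: the models
behind each stage, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the places where the
design was genuinely open.

## Normalization

Expression is normalized **to a reference sample** over a housekeeping panel:
the `panel_size` miRNAs detected in *every* sample with the lowest variance of
log expression (ties broken lexicographically). Defaults are 50 miRNAs for
counts and 40 for Ct — the panel sizes used on the two platforms this design
comes from. For counts the per-sample factor is the aggregate of miRNA-wise
ratios `x[i, j] / x[i, ref]`; for Ct data it is the aggregate of Ct
differences. The aggregator is the **median** by default (`aggregate =
"mean"` is available): the source procedure is described only as a comparison
over the panel, and the median is robust to a few discordant panel members.
The default reference is the sample with the most detected miRNAs — any
fixed, data-independent-given-the-matrix rule works, and this one maximizes
usable comparisons; it is overridable.

Counts are divided by their factor and log2-transformed with a **pseudocount
of 1** so structural zeros stay finite. The pseudocount is applied after the
factor, which makes the normalization exactly scale-equivariant on strictly
positive data at `pseudocount = 0` and equivariant up to the pseudocount
otherwise. Normalized Ct values are reported as `-(Ct - shift)` so that
larger always means more abundant and differences are log2 fold changes on
both platforms. The factor of the reference sample is exactly 1 (counts) or
0 (Ct); re-normalizing factor-corrected data returns factors of exactly 1/0
(idempotence holds at the factor level — the published output is log2-scale,
so "re-running" the count normalization on it is not type-correct).

The red-blood-cell miRNAs miR-451a, miR-144-3p and miR-144-5p track blood
contamination (more frequent in tumor samples) rather than epithelial
biology; `exclude_markers()` removes them before any panel selection, testing
or classification.

## Detection, dropout, and why tests use detected values only

A count is "detected" when positive; a Ct value when not missing (instruments
report reactions above the detection ceiling as undetected).
`detection_filter()` keeps miRNAs detected in ≥ 40% of samples for counts (up
to 60% zeros tolerated) and in *more than* 60% for Ct, matching the wording
of the two platform conventions; a threshold of 0 keeps everything.

Structural dropout creates a specific hazard on the counts platform: a zero
enters the log2 matrix at `log2(1) = 0`, typically 6–10 log2 units below the
miRNA's detected values. Left in place, a single dropout inflates the
within-class variance enough to mask a genuine 4-fold effect (t drops from
~6 to ~1.5 in our simulations). The package therefore treats detection as
first-class: the detection mask travels with the normalized matrix, the
per-miRNA t-tests (differential expression and classifier feature selection)
use **detected measurements only** — exactly as the Ct platform already must,
since undetected reactions are missing there — and the classifiers **impute
undetected entries with the training-fold feature mean**, a class-agnostic
neutral value that cannot leak label information. Under
missing-completely-at-random dropout the detected-only class means are
unbiased, so fold-change estimates are unaffected in expectation. `detected_frac`
is reported per miRNA so borderline calls are visible.

## Differential expression

Per-miRNA two-sample t-tests on normalized log2 values use the
**pooled-variance** statistic by default (`var_equal = FALSE` gives Welch):
the class-comparison idiom of the array-analysis suite this pipeline mirrors
names neither, and at 7–17 samples per class the pooled form is the
conventional default. P-values are two-sided; FDR control is
Benjamini–Hochberg across all tested miRNAs. The fold change is
`2^(mean(tumor) - mean(normal))` of the normalized values — the linear
tumor/normal ratio for counts, the ΔΔCt-style fold change for qPCR.
Signatures are gated by `q < q_max` and at least `min_fold`-fold change in
either direction (defaults 0.007 and 2, the gate used for the pathway
analysis).

The **rank product** is the distribution-robust companion: for every
tumor × normal sample pair, miRNAs are ranked by the pairwise log-ratio, and
the statistic is the geometric mean of a miRNA's ranks across pairs, computed
separately for up- and down-regulation. Significance comes from label
permutations with add-one smoothing, `rp_p = (1 + #{permuted rp ≤ observed})
/ (n_perm + 1)` (default `n_perm = 1000`), so p-values are never zero; the
reported two-sided value doubles the better directional p-value
(Bonferroni over the two directions), capped at 1. Because the statistic
ranks pairwise log-*ratios*, it is invariant to per-sample shifts and to any
common positive rescaling (exactly the transformations normalization
applies), but not to arbitrary per-sample monotone transformations — a
rank-within-sample variant would be, but would no longer be the classical
ratio-based statistic implemented here.

## Classification

All seven algorithms share one feature-selection step: miRNAs with two-class
t-test `p < alpha` on the training data, weighted by their t-statistics; if
nothing passes, the single smallest-p miRNA is used so a classifier always
exists.

* **CCP** — compound covariate `c_s = Σᵢ tᵢ x_is`; threshold at the midpoint
  of the class means of `c`.
* **BCCP** — one-dimensional Gaussians fitted to `c` per class (per-class
  standard deviations, pooled when a class has a single sample); posterior by
  Bayes' rule with equal priors by default.
* **DLDA** — per-feature pooled within-class variances `σᵢ²`; classify by
  `argmin Σᵢ (xᵢ - μᵢₖ)² / σᵢ²`.
* **NC** — nearest Euclidean centroid (DLDA with unit variances).
* **kNN** — Euclidean, k ∈ {1, 3}, majority vote (k = 3 cannot tie with two
  classes; even k is not offered).
* **SVM** — linear kernel, cost fixed at 1, via `e1071`.

Exact ties — a score of zero, a sample equidistant from both centroids, equal
kNN distances at the neighbourhood boundary — resolve deterministically
toward "normal" (the clinically conservative call for a screening tool).

`loocv()` nests everything: for each held-out sample, the significance
threshold α is chosen from `alpha_grid` (default {0.05, 0.01, 0.005, 0.001,
5·10⁻⁴, 10⁻⁴}) by an **inner** leave-one-out accuracy over the remaining
samples, ties toward the smaller (stricter) α; features, weights and the
model are then refit at that α on those samples only. The held-out sample
therefore never influences its own fold's selection, threshold, weights or
imputation means — corrupting its values changes nothing about its fold's
classifier, a property the test suite asserts directly. Inner folds whose
remaining samples cannot support a t-test (a class absent, or fewer than
three samples) are skipped, which lets LOOCV run down to n = 4.

The ROC score is oriented so larger = more tumor-like: the BCCP posterior,
the signed discriminant margin for CCP/DLDA/NC/SVM, the tumor vote fraction
for kNN (which of these generated the original study's curves is not
recoverable; the margin/posterior is the standard choice). ROC points come
from a threshold sweep with tied scores grouped; the trapezoidal AUC then
equals the Mann–Whitney concordant-pair fraction with ties counted ½.
`external_validate()` applies a frozen model — no re-selection, no re-fitting,
imputation means included — to an independent cohort.

## Pathway enrichment and the random-set negative control

The gene list for enrichment is the union of validated target genes over the
signature miRNAs. Each pathway is tested with the one-sided hypergeometric
(Fisher exact) upper tail `P(X ≥ k)` after intersecting the pathway with the
gene universe; the default universe is the union of all pathway genes and all
mapped target genes (the original tool's internal universe is unknown, and
this choice is reproducible from the inputs alone). `k = 0` gives p = 1; the
computation is `stats::phyper`, which sums in log space.

Curated target databases over-represent cancer and cell-cycle pathways, so a
signature-agnostic pathway can reach astronomical significance. The filter
re-runs the identical analysis for `n_sets` random draws of `set_size` miRNAs
(defaults 20 and 11, matching the original negative-control design, with
p-cutoff 10⁻⁶) and retains only query pathways significant in **zero** null
runs ("appeared in a negative control" = significant at the same cutoff in at
least one run; `min_null_hits` exposes a laxer threshold). Query miRNAs are
eligible for the draws by default — the draw universe is the full catalogue
of expressed miRNAs, not the signature — and `exclude_query = TRUE` is
available. With a fixed seed the draw stream is sequential, so increasing
`n_sets` can only shrink or preserve the retained set. No multiplicity
correction is applied across pathways beyond the fixed cutoff, matching the
original design; whether that tool corrected internally before its cutoff is
unstated.

## The synthetic-data generator

`simulate_counts()` draws gamma-Poisson (negative binomial) counts with
log-normal baseline means across miRNAs (meanlog `log(200)`, sdlog 1.8 —
several orders of magnitude, as small-RNA libraries show), per-sample
library-size factors uniform on [1, 3] (a 3× spread; the source reports no
library-size statistics, so this is a generator choice), NB dispersion 0.2
(typical of small-RNA-seq between-sample variability), independent Bernoulli
dropout (`zero_inflation`, default 0.15), planted fold changes with direction
randomized 50/50 (the real signature contains both directions), and the three
RBC markers multiplied by `rbc_spike` (default 8) in tumor samples only.
Before dropout, each planted miRNA's expected tumor/normal mean ratio equals
its planted fold change. Defaults mirror the sequencing cohort: 20 tumor vs
7 normal samples, ~450 miRNAs, 13 planted.

`simulate_ct()` maps the same latent model to the cycle scale:
`Ct = 36 - log2(abundance)` plus a per-sample offset (sd 0.75 cycles, input
variation) and replicate noise (sd 0.5 cycles), censored above `ct_ceiling`
(default 40); a planted fold `f` appears as a `-log2(f)` cycle difference.

`simulate_annotation()` builds a target map over a 2000-miRNA catalogue (the
profiled panel is a subset — negative-control sets are drawn from the pool of
miRNAs expressed in human cells, which is much larger than any one panel's
coverage) and a pathway collection with two planted structures: the planted
pathway's genes are over-represented among targets of the planted miRNAs
(strength `enrichment`, default 0.8), and a "promiscuous" pool (three
pathways' genes) is drawn at an elevated rate by *every* miRNA, emulating the
database bias the negative-control filter exists to remove.

What the generator does **not** emulate: batch effects, abundance-dependent
dropout (real non-detection concentrates in low-abundance miRNAs; here it is
uniform, which is *harsher* on the universal-detection panel), isomiR/arm
structure, and sample-quality gradients. Passing tests therefore show that
the statistics behave correctly under a faithful small-RNA noise model with
known truth — not that any particular clinical accuracy will transfer.

## Study-scale choices in the tests and acceptance script

Simulation studies run at the cohort scales of the motivating study:
classification at 10 + 10 samples × 400 miRNAs with 15 miRNAs planted at
4-fold and 10% dropout; differential-expression recovery on the Ct platform
at 20 + 17 samples with 11 planted miRNAs (the scale that produced the
q < 0.007, ≥ 2× signature), with 5% dropout — calibrated to the observed
fact that a 40-miRNA panel was detectable in every one of 37 qPCR samples,
which is impossible at 10% independent dropout; external validation trains
on a 10 + 10 split and freezes the model for an independent 20 + 10 split of
the same dataset. At these scales only ~50 of 400 miRNAs are universally
detected, so the studies pass `panel_size = 30` (counts) explicitly rather
than the platform default of 50. Null calibration uses 20 independent null
simulations; because estimated normalization factors correlate features
within one dataset, the p-value uniformity check (Kolmogorov–Smirnov) is
evaluated as the median over independent simulations rather than on a single
draw. The negative-control filter is evaluated over 40 seeded runs with 20
random sets of 11 miRNAs at p < 10⁻⁶.

## Known limitations

* No count-model tests (negative-binomial GLMs), paired designs, or covariate
  adjustment; the t-test-on-log2 pipeline is the design being implemented.
* Classification is strictly two-class; there is no "unclassified" band by
  default (binary calls match the original reporting) — BCCP exposes the
  posterior if a caller wants one.
* Ct matrices with missing values feed classification through the same
  training-mean imputation; heavy non-random censoring will bias centroids.
* The enrichment universe and the target map are taken at face value from
  their files; database-version effects on real target maps are out of scope.
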