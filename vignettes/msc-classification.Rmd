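---
title: "Deriving and applying a stable MSC transcriptional signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and applying a stable MSC transcriptional signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msclassify)
```

## The problem

Mesenchymal stromal cells (MSC) lack specific surface markers: the
antibody panels in routine use are shared with fibroblasts, endothelial
progenitors and haematopoietic cells, and their behaviour varies between
laboratories. A transcriptome-level classifier trained across many public
datasets can do better, but such a compendium spans microarray platforms
with different probe sets, background levels and dynamic ranges, and small
per-study sample sizes make naive marker lists irreproducible.

`msclassify` implements the full pipeline for this setting: it integrates
gene-by-sample log2 expression matrices from multiple datasets while
tracking which genes each platform actually measures, normalizes every
sample independently so datasets can be added or removed without
renormalizing anything, derives a compact multi-component gene signature
whose members are required to be *stably* selected across repeated
subsamplings of the data, and scores new samples with an ensemble that
reports a confidence interval and a three-way MSC / non-MSC / unknown
call.

## Data integration and presence tracking

Expression input is probe- or gene-level TSV, one dataset at a time. When
several probes map to one gene, the probe with the highest mean expression
across the dataset's samples is kept (ties go to the lexicographically
first probe ID, so the collapse is deterministic). Merging takes the union
of gene sets; a gene not measured by some dataset's platform is zero-filled
for that dataset's samples and flagged `FALSE` in a presence mask that
accompanies the matrix from then on. Genes measured in fewer than half the
samples — `ceiling(n/2)`, the majority convention for odd `n`; "measured"
means platform coverage, not any expression threshold — are dropped before
normalization.

## Per-sample normalization

Each sample is rescaled by the cumulative proportion of its total
expression. With the sample's values sorted decreasingly as
$x_{(1)} \ge \dots \ge x_{(p)}$ and $S = \sum_j x_j$, the gene at rank $k$
receives

$$y_{(k)} = 1 - \frac{\sum_{j \le k} x_{(j)}}{S} \in [0, 1),$$

mapped back to gene order. The transform is a pure function of one sample:
no other sample, dataset or cohort statistic enters, which is what makes
incremental integration and cross-validation cheap. Conventions that the
definition leaves open are fixed as follows: negative values (possible
after some background corrections) are shifted by the sample minimum
before transforming, because a cumulative proportion needs non-negative
mass; ties are broken by (value decreasing, gene ID ascending) with each
tied gene keeping its own rank, trading exactness of an unspecified
convention for determinism; zero-filled absent genes carry zero mass and
always map to 0. Note that monotonicity is strict only among positive
values — genes with zero expression all collapse to 0.

## The sparse discriminant model

Class membership is encoded as an $n \times 2$ indicator matrix $Y$
(columns MSC, non-MSC). Columns of $X$ (samples × genes) are centered and
scaled to unit variance once, before the first component; genes with zero
variance get scale 1 and are barred from the loadings. For components
$h = 1, \dots, H$:

1. form the cross-covariance $M_h = X_h^\top Y_h$ on the current deflated
   matrices;
2. take its dominant left singular vector $u_h$ (computed by power
   iteration on the $2 \times 2$ Gram matrix $M_h^\top M_h$ with a fixed
   all-ones start and tolerance $10^{-12}$ — deterministic and
   dependency-free);
3. sparsify: with $\lambda$ the $(k_h + 1)$-th largest $|u_{hj}|$
   (`keepX[h]` $= k_h$), replace $u_{hj}$ by
   $\mathrm{sign}(u_{hj})(|u_{hj}| - \lambda)_+$ and renormalize, leaving
   at most $k_h$ nonzero gene loadings (tied magnitudes fall back to a
   deterministic top-$k_h$ selection);
4. score $t_h = X_h u_h$, orient the sign so the MSC class mean score is
   positive, store the regression coefficients of $Y_h$ on $t_h$, and
   deflate both $X_h$ and $Y_h$ by their regression on $t_h$.

With sparsity disabled this reduces exactly to PLS-DA, and the
component-1 loading equals the dominant left singular vector of the
centered cross-covariance — the oracle the test suite checks against, in
addition to an independent sPLS-DA implementation. Deflating $Y$ by
regression (rather than not deflating it) is a choice; the dense
equivalence test pins down its consequences.

A new sample's score is the predicted MSC-indicator value: the class
proportion plus $\sum_h t_{h,\text{new}} \, c_h$, clipped to $[0, 1]$. A
signature gene absent from the input is imputed at the stored training
center, so after centering it contributes exactly zero to every component
— an unmeasured gene is treated as carrying no evidence either way, not
as evidence of zero expression. Prediction refuses inputs missing more
than half the model's genes.

## Stability selection

A single fit's gene selection reflects whichever datasets dominate the
training set. The pipeline therefore refits the model on `M` subsamples
drawn *within every (dataset, class) stratum* (fraction 0.8 without
replacement; strata of size 1 are always retained), and records, per gene
and component, the fraction of fits selecting it. Stratifying by dataset
is what operationalizes "not reliant on one dominant source or platform".
Two caveats the tests document: subsamples at fraction 0.8 overlap
heavily, so selections are correlated across iterations and a lucky noise
gene can recur well above the naive binomial `keepX/p` level — diffuse
profiles show as low *typical* frequencies, not a low maximum; and the
per-iteration seed is derived deterministically (`seed + m`, with failed
fits redrawn at a derived offset), so the whole profile is reproducible.

## Signature refinement

Candidates are ordered per component by decreasing selection frequency and
grown as nested cross-component sets: component 1's candidates first, then
component 2's appended, and so on. Each set's quality is its out-of-bag
balanced classification error — refit the model restricted to the set on
each retained subsample, classify that subsample's held-out complement by
the larger predicted indicator, and average the two class-wise error
rates. A candidate set is accepted when a one-tailed paired t-test across
the `M` error vectors shows it improves on the **last accepted** set at
`alpha_refine` (default 0.05; `alpha = 1` degenerates to keeping every
candidate).

Testing against the last accepted set, rather than the immediate
predecessor, was a deliberate choice made after observing the error
trajectories: under per-gene batch offsets the out-of-bag error is not
monotone in set size, and a single gene with unlucky offsets would
otherwise terminate growth while the error is still falling steeply.
The cumulative (cross-component) evaluation has a second consequence:
a component whose genes never improve the joint accuracy — typically one
tracking batch rather than class structure — contributes no genes. Genes
are unique across the signature; each is annotated with its selection
frequency, its Pearson correlation to its component's score in a final
full-data fit restricted to the signature, and its loading sign.

## Ensemble scoring and the three-way call

The training matrix restricted to the signature is refit on `M` stratified
subsamples (each component's `keepX` equals its assigned gene count).
Every sample scored against the ensemble receives `M` scores; its 95%
confidence interval is the percentile interval (type-7 linear
interpolation, for bit-reproducibility) and the audit trail of each
decision is the report row `mean_score, ci_low, ci_high, call`.

Thresholds come from the labelled training samples' mean scores:
`t_high` is the 1% quantile of the MSC scores (99% of MSC lie above it)
and `t_low` the 99% quantile of the non-MSC scores. The interval between
them is the uncertainty region. The primary rule calls MSC when the CI
lower bound lies strictly above `t_high`, non-MSC when the upper bound
lies strictly below `t_low`, and unknown otherwise; an alternative
pass-rate rule (MSC when at least 95% of the `M` scores exceed `t_high`)
is provided because both formulations are defensible and neither
subsumes the other — they agree on well-separated samples, which the
tests verify. Training samples are scored by all `M` submodels, including
those whose subsample contained them; an out-of-bag option (`oob = TRUE`)
restricts each sample to the submodels that excluded it, which spreads
the training score distributions and narrows the uncertainty region —
useful as a sensitivity check, but the all-submodel variant is the
default. If the two quantiles cross, the region is empty, the
`empty_overlap` flag is set, and every call is definite.

When scoring new data through `cmd_score`, the input is first restricted
to the ensemble's stored training gene universe before the YuGene
transform, so cumulative proportions are computed over the same gene set
as in training; universe genes the input does not measure carry zero mass
either way and are center-imputed at prediction.

## Fixed marker panels and per-gene tests

`evaluate_panel` benchmarks a fixed gene list with the same machinery the
signature is judged by — non-sparse 2-component PLS-DA over `M` stratified
subsamplings, held-out samples classified by the larger predicted
indicator, errors pooled over all held-out samples so the overall error is
exactly the sample-weighted combination of the class-wise errors.
`marker_ttest` applies a Welch two-tailed t-test per gene at the
genome-wide threshold $10^{-6}$; Welch's unequal-variance form is used
because the two classes are typically very unbalanced. Zero-variance
degenerate genes report $p = 1$.

## The synthetic compendium

Because the real multi-study compendium cannot be bundled, the package
generates one with known ground truth. Per gene, a baseline log2
expression is drawn uniformly on $[4, 12]$ (the usual dynamic range of
background-corrected arrays). Each dataset adds a *per-gene* offset with
standard deviation `dataset_shift_sd` — per-gene, not scalar, because
probe-affinity differences between platforms act gene by gene, and a
scalar batch shift would be removed by almost any normalization, making
the integration problem trivial. The default `dataset_shift_sd = 1.0`
equals the within-class noise: cross-platform offsets in real microarray
compendia are at least as large as typical biological effects, which is
exactly why per-sample normalization and stability selection are needed.
A set of `n_informative` genes (default 15) gains `effect_size` (default
1.5) noise-SD units in MSC samples; Gaussian noise (SD 1) is added on the
log2 scale; 10% of genes per dataset are marked unmeasured and
zero-filled. Mixture samples interpolate the two class mean profiles at
$\lambda \in \{0.25, 0.5, 0.75\}$ with fresh noise, emulating cultures
captured mid-differentiation, and are labelled unknown.

The gene-level profiles (baseline, informative set, effects) are a
deterministic function of the config seed, so `simulate_dataset` can draw
additional datasets — fresh offsets, missingness and noise — from the
same underlying biology, the situation of scoring a newly published study.
`simulate_transition` produces an ordered differentiation-style series
from the class mean profiles plus fresh noise, without a batch offset or
missingness, since a transition series is a single experimental series.

What the generator does *not* emulate: probe-level intensity
distributions, platform-specific mean-variance relationships, correlated
gene modules, RNA-seq counts, or class structure of rank above one (all
informative genes shift in the same direction). Passing tests on this
generator therefore demonstrate the pipeline's mechanics and its
robustness to additive per-gene batch structure — not performance on real
compendia.

## Numerical and design choices, in one place

* Power iteration with fixed start, tolerance $10^{-12}$; no randomness in
  the fit itself.
* Zero-variance genes: scale set to 1, loading forced to 0.
* All quantiles: type 7.
* Scores clipped to $[0, 1]$; calls use strict inequalities against the
  thresholds.
* Tie-breaks everywhere are lexicographic (probe IDs, gene IDs) or
  positional, under C-locale radix ordering, so results do not depend on
  the session locale.
* Coverage is accepted down to 0.5 (where the thresholds are the class
  medians); the pipeline default is 0.99.
* Every stochastic stage takes a master seed and derives per-iteration
  seeds additively; training twice with one seed yields byte-identical
  artifact files, which the tests assert.
* Serialized ensembles store doubles at 17 significant digits so a round
  trip through JSON is bit-exact, and carry a format version that is
  checked on read.

The test suite runs the full pipeline at `p = 1000` genes, 4 datasets of
40 samples and `M = 100` subsamplings — large enough for the recovery and
classification properties to be stable, small enough to run routinely —
with smaller designs for unit-level checks.

## Known limitations

* A dataset's per-gene offsets shift all its samples' scores coherently;
  with few training datasets this dataset-level luck dominates held-out
  error far more than per-sample noise. More training datasets, not more
  samples per dataset, is what reduces it.
* The decision thresholds are extreme quantiles of the training score
  distributions; with tens of training samples per class they are pinned
  by the one or two most extreme samples and are correspondingly unstable.
* The refinement t-test treats the `M` subsample errors as paired
  observations; because subsamples overlap, the test is anti-conservative,
  and marginal genes — including genes tracking batch structure shared by
  the training datasets — can be admitted. The out-of-bag error cannot
  detect structure common to all training datasets.
* Multiclass designs, kernel variants and missing-value imputation beyond
  zero-fill/center-imputation are out of scope.
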