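---
title: "Personalized pathway dysregulation scores for metabolomics diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized pathway dysregulation scores for metabolomics diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdsdiag)
```

## The problem

Blood metabolomics is an attractive substrate for cancer diagnosis, but
individual metabolite biomarkers replicate poorly across cohorts and
platforms.  `pdsdiag` implements a pathway-level alternative: instead of
feeding metabolite intensities to a classifier directly, it first
summarizes each metabolic pathway, per sample, into a single scalar —
the *pathway dysregulation score* (PDS) — and builds the diagnostic
model on those pathway features.  Metabolites in the same pathway tend
to be dysregulated together, so the pathway summary is expected to be a
more stable feature than any one of its members.

The pipeline has four stages, each an exported function family:

1. **Pathway mapping** (`read_gmt()`, `standardize_names()`,
   `map_pathways()`): metabolite names are standardized to HMDB
   identifiers through a synonym table, and a GMT master file assigns
   metabolites to pathways.  A pathway is *usable* when at least
   `min_size` of its members were measured.
2. **PDS computation** (`compute_pds()`): per usable pathway, a
   principal curve is fitted in the pathway's reduced metabolite space
   and every sample is scored by its normalized arc-length position.
3. **Feature selection** (`consensus_select()`,
   `mutual_information()`): correlation-based feature selection (CFS)
   inside a stratified 10-fold loop; only pathways selected in all ten
   folds are retained.
4. **Classification and evaluation** (`train_classifier()`,
   `evaluate_classifier()`, `run_model()`): a ridge-penalized logistic
   model on the retained pathway scores, evaluated with AUC,
   sensitivity, specificity, MCC and F1 on the training set and on
   independently scored test sets.

## The pathway dysregulation score

For one pathway with $m$ measured metabolites over $n$ samples, the
submatrix is preprocessed as follows:

* **log transform** (default on): MS intensities are approximately
  log-normal; the curve is fitted in log space.
* **median imputation** per metabolite over the observed samples;
* **z-scoring** of each metabolite over all samples, which also makes
  the score invariant to per-metabolite rescaling (units, calibration);
* **PCA reduction** to the smallest dimension $d$ reaching
  `variance_kept` (default 0.90) cumulative explained variance, capped
  at `min(m, n - 1, pc_cap)` with `pc_cap = 5`.  Component signs are
  standardized so results do not depend on sample order.

A smoothed principal curve is then fitted by Hastie–Stuetzle
alternation: initialize the arc-length parameter $\lambda$ by projection
onto the first principal-component line, then repeat

1. smooth each coordinate against $\lambda$ with a cubic smoothing
   spline (`spar = 0.75`);
2. project all points onto the resulting polyline and re-parameterize
   by arc length,

until the relative change in the summed squared projection residuals
falls below `tol` ($10^{-4}$) or `max_iter` (50) is reached.  The raw
alternation is not monotone — on noisy clouds the residual sum can jump
between iterates — so the fitter tracks the best (lowest-sse) iterate
seen and stops after five consecutive non-improving iterations,
returning that best iterate.  This makes the fit reproducible: tiny
floating-point perturbations no longer select a different tail iterate.

Every sample's $\lambda$ is min–max normalized to $[0, 1]$.  The curve
has no intrinsic direction, so it is oriented by the *control* samples:
the orientation with the smaller median control position is chosen
(ties: smaller mean; then keep).  A score near 0 therefore means
"metabolically like the normal samples", a score near 1 "maximally
aberrant along this pathway's main axis of variation".  By default the
curve is fitted on **all** samples and controls are used only for
orientation, matching the reference algorithm for this score family;
`fit_on = "controls"` switches to fitting on controls only and
projecting the rest, which matches a stricter reading of "constructed
from the normal samples".  Both are exposed because the published
description is ambiguous; the default keeps case projections
on-support.

Degenerate pathways (all-constant metabolites, or all samples
projecting to one point) are dropped and recorded in
`pds_diagnostics()` rather than failing the whole run.

## Feature selection

CFS scores a candidate subset $S$ of $k$ pathway features by

$$\mathrm{merit}(S) = \frac{k\,\overline{|r_{cf}|}}
  {\sqrt{k + k(k-1)\,\overline{|r_{ff}|}}},$$

with $\overline{|r_{cf}|}$ the mean absolute (point-biserial)
feature–class correlation and $\overline{|r_{ff}|}$ the mean absolute
pairwise feature–feature correlation: relevance rewarded, redundancy
penalized.  Correlations are Pearson on the continuous scores rather
than a discretized variant: PDS features are continuous and bounded,
and discretization would add an instability with no benefit here.  The
search is best-first forward with a stale limit of 5 and deterministic
lower-index tie-breaks.

`consensus_select()` wraps the search in seeded, class-stratified
10-fold cross-validation and retains only features selected in **all
ten** folds.  If nothing survives — typical when there is no signal —
downstream model fitting degrades explicitly to an intercept-only
logistic model, i.e. a constant predictor with AUC 0.5: the pipeline's
way of saying "no stable feature was found" instead of overfitting
noise.

Retained features are ranked by mutual information with the class,
estimated by equal-frequency discretization into 4 bins and the plug-in
estimator, reported in bits (at most 1 bit for a binary class).

## Classifiers and metrics

The headline model is logistic regression fitted by ridge-penalized
IRLS ($\lambda = 10^{-4}$ on standardized features, intercept
unpenalized) so that separable training data still yields finite
coefficients.  SVM (radial) and random forest are available behind the
same interface for model comparison (`compare_classifiers()`), both
seeded for determinism.

Evaluation reports midrank AUC (identical to the Mann–Whitney
statistic, ties counted one half), plus sensitivity, specificity, F1
and MCC at a fixed probability cutoff of 0.5 (no operating point is
optimized).  MCC is defined as 0 when a denominator factor vanishes.
`univariate_models()` fits one-feature logistic models and two-sided
Welch t-tests for per-feature diagnostic potential.

## Study-design orchestration

`split_cohort()` performs the per-class 80/20 split with round-to-
nearest counts (132 cases / 76 controls give 106 + 61 training and
26 + 15 test samples).  `run_model()` computes PDS matrices **per
dataset** — each test cohort is scored within itself, using its own
controls — selects features and trains on the training set only, and
evaluates everywhere; deleting the test sets provably does not change
the trained model.  `stage_filter = c("I", "II")` restricts training
cases to early stages for an early-stage model.
`run_baseline_metabolite_model()` applies the identical selection and
classification machinery to log-z-scored metabolite columns, giving the
metabolite-level baseline for head-to-head comparison, and
`sensitivity_analysis()` reruns selection on a random pathway subset
(default half, round-to-nearest, so 101 usable pathways keep 51) to
probe how performance depends on pathway-pool size.

One `seed` in `pds_config()` drives the split shuffle, the fold
assignment and the stochastic learners, so two runs from the same
configuration are byte-identical.

## The synthetic cohort generator

Because the deposited study cohorts cannot be bundled, the package
ships a generator (`cohort_spec()`, `simulate_cohort()`) that emulates
their structure and makes every stage testable end-to-end:

* controls are drawn per pathway block from a zero-mean equicorrelated
  Gaussian (`rho = 0.5` within a pathway) on the log scale with unit
  variance, then exponentiated to positive MS-like intensities;
* each case carries a latent progression $t \sim U(0,1)$; in planted
  pathways every member metabolite is shifted by
  $\mathrm{sign}_j \cdot \delta \cdot t$ (z-score units,
  `delta = 2` by default), with 30 % of members shifted downward
  (`sign_mix = 0.3`) the way real pathway perturbations mix up- and
  down-regulated metabolites;
* tumor stage is derived from $t$ with the stage mix of the emulated
  plasma cohort, so later stages are more dysregulated and early-stage
  modelling is meaningful;
* cells are masked missing completely at random (5 % default); an
  intensity-dependent missingness mechanism is deliberately out of
  scope.

Defaults emulate a 132-case / 76-control plasma cohort with 30
pathways of 5 metabolites, 5 of them planted.  `write_cohort()` /
`read_cohort()` round-trip the cohort through plain CSV/TSV/GMT/JSON.

What the generator does **not** emulate: batch effects, platform
differences between cohorts, annotation errors, non-Gaussian tails, and
correlation *between* pathways beyond optional membership overlap.
Passing tests on synthetic cohorts therefore demonstrate algorithmic
correctness and honest end-to-end behaviour, not clinical performance
on real data.

A structural consequence worth knowing: the within-pathway
equicorrelation is class-independent noise, and at `rho = 0.5` its
shared factor carries more variance than the planted shift, so an
unsupervised one-dimensional summary like the PDS mixes the two.  Under
these conditions the synthetic planted-pathway problem has a modest
ceiling for any method building on per-pathway scores — a property of
the simulated geometry to keep in mind when interpreting absolute
numbers from the generator (directional and comparative properties are
unaffected).

## Numerical choices and edge cases

* Projection onto the fitted polyline is exact (vectorized
  point-to-segment distances), with first-match tie-breaking.
* `smooth.spline` uses at most 40 knots for speed on large cohorts and
  falls back to a straight least-squares line when fewer than four
  distinct parameter values are available.
* Samples are internally sorted by `sample_id` before PDS computation
  and mapped back afterwards, making sample order provably irrelevant.
* Zero-variance metabolites are dropped with a warning; zero-variance
  features get correlation 0 in CFS and p-value 1 in the univariate
  table.
* A 1-D pathway (after reduction) uses the identity curve; its PDS is
  the min–max-normalized coordinate.
* `min_size` defaults to 3 because a principal curve over fewer
  features is degenerate; the published pathway count cannot be
  reproduced without the real master file, so the threshold is a
  configuration knob, not a claim.

## Problem sizes used by the test-suite

The packaged tests and the acceptance script run the full pipeline on
simulated cohorts of 100 cases + 60 controls with 30 pathways (5
planted), across 10–20 seeds per property, and smaller cohorts for
unit-level properties.  These sizes exercise every code path in a few
minutes while keeping per-seed sampling noise within the asserted
bands.

## Known limitations

* The PDS is unsupervised within each pathway; it cannot down-weight
  class-independent correlated variation inside a pathway (see the
  generator note above).
* CFS consensus with the strict all-folds rule is conservative: with
  correlated informative features it may retain a subset of them.
* The fixed 0.5 probability threshold makes sensitivity/specificity
  scale-dependent when a test cohort's score distribution shifts
  relative to training; AUC is the robust cross-cohort metric.
* Name standardization is exact (after normalization); misspelled
  synonyms stay unmapped by design rather than being fuzzy-matched.
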